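test_that("one-dimensional jitter puts all variance on PC1", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  xyz <- t(vapply(1:50, function(f) {
    x <- ref; x[, 1] <- x[, 1] + rnorm(1)   # rigid-free: same atoms jittered
    as.numeric(t(x))
  }, numeric(30)))
  # jitter each atom independently along x only
  xyz <- t(vapply(1:200, function(f) {
    x <- ref; x[, 1] <- x[, 1] + rnorm(10, sd = 0.5)
    as.numeric(t(x))
  }, numeric(30)))
  traj <- toy_trajectory(xyz)
  pm <- covariance_pca(traj, 1:10, reference = NULL)
  # variance only in x coordinates: fractions of PCs beyond rank 10 are 0
  expect_equal(sum(pm$fractions[1:10]), 1, tolerance = 1e-9)
  expect_equal(sum(pm$values), pm$trace, tolerance = 1e-8 * pm$trace)
  # eigenvectors have no y/z components
  ycols <- as.vector(rbind(seq(2, 30, 3), seq(3, 30, 3)))
  expect_lt(max(abs(pm$vectors[ycols, 1:10])), 1e-8)
})

test_that("prescribed anisotropic variances are recovered", {
  set.seed(2)
  ref <- matrix(0, 1, 3)
  xyz <- cbind(rnorm(1e4, sd = 3), rnorm(1e4, sd = 2), rnorm(1e4, sd = 1))
  traj <- toy_trajectory(xyz)
  pm <- covariance_pca(traj, 1L, reference = NULL)
  expect_equal(pm$values, c(9, 4, 1), tolerance = 0.1)
  # isotropic jitter: leading eigenvalues equal within sampling error
  iso <- toy_trajectory(matrix(rnorm(3e4, sd = 2), 1e4, 3))
  pmi <- covariance_pca(iso, 1L, reference = NULL)
  expect_lt(diff(range(pmi$values)) / mean(pmi$values), 0.1)
})

test_that("eigenvectors are orthonormal with a deterministic sign", {
  set.seed(3)
  tr <- generate_correlated_ensemble(
    ensemble_spec(matrix(rnorm(18, sd = 5), 6, 3), diag(6), 0.4, 300L, 5L))
  pm <- covariance_pca(tr, 1:6, reference = NULL)
  G <- crossprod(pm$vectors)
  expect_equal(G, diag(ncol(pm$vectors)), tolerance = 1e-8)
  expect_true(all(vapply(seq_len(ncol(pm$vectors)), function(k)
    pm$vectors[which.max(abs(pm$vectors[, k])), k] > 0, logical(1))))
  expect_equal(sum(pm$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pm$values) <= 1e-12))
})

test_that("projections satisfy the PCA identities", {
  set.seed(4)
  tr <- generate_correlated_ensemble(
    ensemble_spec(matrix(rnorm(24, sd = 5), 8, 3), diag(8), 0.5, 400L, 6L))
  pm <- covariance_pca(tr, 1:8, reference = NULL)
  P <- project_frames(tr, pm, 5)
  for (k in 1:5)
    expect_equal(var(P[, k]), pm$values[k], tolerance = 1e-6 * pm$values[1])
  # projecting the mean structure gives the origin
  mean_traj <- toy_trajectory(matrix(pm$mean, nrow = 1))
  expect_equal(as.numeric(project_frames(mean_traj, pm, 3)), rep(0, 3),
               tolerance = 1e-9)
  expect_error(project_frames(tr, pm, k = 100), "exceeds")
})

test_that("variance captured by PC1+PC2 does not grow with added noise dims", {
  set.seed(5)
  base <- generate_correlated_ensemble(
    ensemble_spec(matrix(rnorm(12, sd = 5), 4, 3),
                  matrix(c(1, .9, 0, 0, .9, 1, 0, 0, 0, 0, 1, 0,
                           0, 0, 0, 1), 4, 4), 0.5, 500L, 7L))
  pm4 <- covariance_pca(base, 1:4, reference = NULL)
  wide <- generate_correlated_ensemble(
    ensemble_spec(matrix(rnorm(24, sd = 5), 8, 3),
                  { C <- diag(8); C[1, 2] <- C[2, 1] <- .9; C },
                  0.5, 500L, 7L))
  pm8 <- covariance_pca(wide, 1:8, reference = NULL)
  expect_lte(sum(pm8$fractions[1:2]), sum(pm4$fractions[1:2]) + 1e-9)
})

test_that("the landscape follows the Boltzmann closed form", {
  # uniform occupancy: Delta G = 0 on every occupied bin
  u <- fel_grid(matrix(5, 3, 3), 300)
  expect_equal(max(abs(u$energy)), 0)
  # a bin at rho_max / e sits exactly kT above the minimum
  g <- fel_grid(c(exp(1), 1), temperature = 300)
  expect_equal(g$energy[1], 0)
  expect_equal(g$energy[2], 0.0019872 * 300, tolerance = 1e-6)
  # pairwise differences are independent of the rho_max normalization
  d <- fel_grid(c(8, 2, 4), 250)
  kT <- 0.0019872 * 250
  expect_equal(d$energy[2] - d$energy[3], -kT * log(2 / 4), tolerance = 1e-9)
  expect_error(fel_grid(c(1, 2), temperature = -10), "positive")
  expect_error(fel_grid(c(0, 0)), "occupied")
})

test_that("fel bins projections with an exact occupied minimum and NA sentinel", {
  set.seed(6)
  P <- cbind(rnorm(2000), rnorm(2000))
  fg <- fel(P, bins = 20)
  expect_equal(min(fg$energy, na.rm = TRUE), 0)
  expect_true(any(is.na(fg$energy)))           # corners are empty
  expect_equal(sum(fg$counts), 2000)
})

test_that("basins of mixtures are found at the generator centers", {
  set.seed(7)
  ref <- matrix(rnorm(18, sd = 6), 6, 3)
  a <- ensemble_spec(ref, diag(6), 0.3, 100L, seed = 1L)
  b <- ensemble_spec(ref + 6, diag(6), 0.3, 100L, seed = 1L)
  mix <- generate_two_state_ensemble(a, b, 0.5, n_frames = 4000L, seed = 2L)
  pm <- covariance_pca(mix, 1:6, reference = NULL)
  P <- project_frames(mix, pm, 2)
  # bimodal PC1 histogram: the two label groups are far apart on PC1
  labs <- attr(mix, "labels")
  sep <- abs(mean(P[labs == 1, 1]) - mean(P[labs == 2, 1]))
  expect_gt(sep, 6 * sd(P[labs == 1, 1]))
  fg <- fel(P, bins = 30)
  # depth threshold ~ 2 kT drowns single-count sampling islands in the
  # tails while leaving the genuine substate wells untouched
  bas <- basin_detect(fg, depth_threshold = 1.2)
  expect_equal(nrow(bas), 2L)
  # basin minima lie near the projected state centers (within 2 bin widths)
  bw <- diff(fg$x[1:2])
  centers <- sort(c(mean(P[labs == 1, 1]), mean(P[labs == 2, 1])))
  expect_equal(sort(bas$pc1), centers, tolerance = 2 * bw)

  # single Gaussian cloud: one basin; threshold above relief: one basin
  single <- fel(cbind(rnorm(3000), rnorm(3000)), bins = 25)
  expect_equal(nrow(basin_detect(single, 1.2)), 1L)
  expect_equal(nrow(basin_detect(fg, 1e3)), 1L)
})
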