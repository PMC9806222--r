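test_that("Coulomb energies hit the standard constant and closed forms", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(X, c(1, 1)), 332.0636, tolerance = 1e-6)
  # opposite unit charges at 3.320636 A: exactly -100 kcal/mol
  X2 <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  expect_equal(coulomb_energy(X2, c(1, -1)), -100, tolerance = 1e-4)
  # dielectric scaling and coincident-atom error
  expect_equal(coulomb_energy(X, c(1, 1), dielectric = 4),
               332.0636 / 4, tolerance = 1e-6)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "coincident")
  # 4-atom toy equals the brute-force double loop
  set.seed(1)
  X4 <- matrix(rnorm(12, sd = 3), 4, 3)
  q4 <- c(0.3, -0.5, 0.8, -0.6)
  pairs <- t(combn(4, 2))
  expect_equal(coulomb_energy(X4, q4), bruteforce_coulomb(X4, q4, pairs),
               tolerance = 1e-10)
})

test_that("Lennard-Jones pairs bottom out at -sqrt(eps_i eps_j)", {
  p <- ff_params(c(0, 0), rstar = c(1.5, 1.9), epsilon = c(0.2, 0.12),
                 gb_radius = 1.5)
  rm_ij <- 1.5 + 1.9
  at_min <- lj_energy(rbind(c(0, 0, 0), c(rm_ij, 0, 0)), p)
  expect_equal(at_min, -sqrt(0.2 * 0.12), tolerance = 1e-12)
  # decay: at 10x the minimum distance the energy is vanishing
  far <- lj_energy(rbind(c(0, 0, 0), c(10 * rm_ij, 0, 0)), p)
  expect_lt(abs(far), 1e-4 * sqrt(0.2 * 0.12))
  # 3-atom toy against the brute-force oracle
  set.seed(2)
  X3 <- matrix(rnorm(9, sd = 4), 3, 3)
  p3 <- ff_params(c(0, 0, 0), c(1.7, 1.5, 2.0), c(0.1, 0.2, 0.05), 1.5)
  expect_equal(lj_energy(X3, p3),
               bruteforce_lj(X3, p3$rstar, p3$epsilon, t(combn(3, 2))),
               tolerance = 1e-10)
  expect_error(lj_energy(rbind(c(0, 0, 0), c(0, 0, 0)), p), "zero distance")
})

test_that("generalized Born reduces to the Born ion and stays additive", {
  # single ion: analytic Born self-energy with the intrinsic radius
  pb <- ff_params(charge = 1, rstar = 1.7, epsilon = 0.1, gb_radius = 2.0)
  e1 <- gb_energy(rbind(c(0, 0, 0)), pb, solvent_dielectric = 80,
                  solute_dielectric = 1, offset = 0)
  expect_equal(e1, -0.5 * (1 - 1 / 80) * 332.0636 / 2.0,
               tolerance = 1e-3 * abs(e1))
  # two identical ions at vast separation: the residual screened pair
  # interaction at 1e6 A is negligible and the sum of self-energies remains
  p2 <- ff_params(c(1, 1), 1.7, 0.1, 2.0)
  e2 <- gb_energy(rbind(c(0, 0, 0), c(0, 0, 1e6)), p2, 80, 1, offset = 0)
  expect_equal(e2, 2 * e1, tolerance = 1e-5)
})

test_that("the pairwise f_GB matches an independent evaluation", {
  set.seed(3)
  X <- rbind(c(0, 0, 0), c(3, 0, 0))
  q <- c(0.6, -0.4)
  alpha <- c(1.6, 1.9)
  mine <- gb_energy(X, q, solvent_dielectric = 80, solute_dielectric = 1,
                    effective_radii = alpha)
  expect_equal(mine, oracle_gb(X, q, alpha), tolerance = 1e-8)
  # several random geometries with supplied radii
  for (k in 1:5) {
    Xk <- matrix(rnorm(12, sd = 3), 4, 3)
    qk <- rnorm(4); ak <- runif(4, 1.2, 2.5)
    expect_equal(gb_energy(Xk, qk, 80, 1, effective_radii = ak),
                 oracle_gb(Xk, qk, ak), tolerance = 1e-8)
  }
})

test_that("GB pair interactions approach screened Coulomb at long range", {
  # at r >> Born radii the pair term tends to -(1 - 1/eps_out) k q_i q_j / r
  q <- c(0.5, -0.8); alpha <- c(1.5, 1.8); r <- 50
  X <- rbind(c(0, 0, 0), c(r, 0, 0))
  pair_gb <- gb_energy(X, q, 80, 1, effective_radii = alpha) -
    gb_energy(rbind(c(0, 0, 0)), q[1], 80, 1, effective_radii = alpha[1]) -
    gb_energy(rbind(c(0, 0, 0)), q[2], 80, 1, effective_radii = alpha[2])
  screened <- -(1 - 1 / 80) * 332.0636 * q[1] * q[2] / r
  expect_equal(pair_gb, screened, tolerance = 0.01 * abs(screened))
})

test_that("descreening shrinks neighbors' effective radii sensibly", {
  p <- ff_params(c(0, 0), 1.7, 0.1, gb_radius = 1.7)
  iso <- born_radii(rbind(c(0, 0, 0)), p[1, ], offset = 0)
  expect_equal(iso, 1.7, tolerance = 1e-12)
  near <- born_radii(rbind(c(0, 0, 0), c(3.5, 0, 0)), p, offset = 0)
  expect_true(all(near > 1.7))       # burial grows the effective radius
  far <- born_radii(rbind(c(0, 0, 0), c(500, 0, 0)), p, offset = 0)
  expect_equal(far, c(1.7, 1.7), tolerance = 1e-6)
  expect_error(born_radii(rbind(c(0, 0, 0)), ff_params(0, 1, 0.1, 0.05)),
               "nonpositive")
})

test_that("Shrake-Rupley areas match closed forms and fine quadrature", {
  # isolated sphere radius 1.6, probe 1.4: 4 pi 3^2
  s1 <- sasa(rbind(c(0, 0, 0)), 1.6, probe = 1.4, n_points = 960)
  expect_equal(s1$total, 4 * pi * 9, tolerance = 1e-9)
  # two far-apart spheres: additivity
  s2 <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.6, 2.0), 1.4, 960)
  iso2 <- 4 * pi * (3.0^2 + 3.4^2)
  expect_equal(s2$total, iso2, tolerance = 1e-9)
  # fused dimer against a 1e5-point quadrature of the same construction
  X <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  coarse <- sasa(X, c(1.6, 1.6), 1.4, 960)$total
  fine <- sasa(X, c(1.6, 1.6), 1.4, 1e5)$total
  expect_equal(coarse, fine, tolerance = 0.01 * fine)
  # burial strictly reduces the area
  expect_lt(coarse, 2 * 4 * pi * 9)
})

test_that("the nonpolar model is the stated linear form", {
  expect_equal(nonpolar_energy(1000, gamma = 0.0072, b = 0), 7.2)
  expect_equal(nonpolar_energy(0, gamma = 0.0072, b = 0.92), 0.92)
  expect_equal(nonpolar_energy(-1500, 0.0072, 0), -10.8)
})

test_that("binding decompositions satisfy the per-frame identities", {
  set.seed(4)
  ref <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(7.0, 0.5, 0), c(10.2, 0.2, 0))
  tr <- generate_correlated_ensemble(ensemble_spec(ref, diag(4), 0.1, 6L,
                                                   seed = 5L))
  par <- ff_params(c(0.4, -0.4, 0.5, -0.5), 1.9, 0.1, 1.6)
  dec <- binding_energy(tr, receptor = 1:2, ligand = 3:4, par,
                        n_points = 400L)
  pf <- dec$per_frame
  expect_equal(pf$dE_gas, pf$dE_ele + pf$dE_vdW, tolerance = 1e-9)
  expect_equal(pf$dG_solvation, pf$dG_GB + pf$dG_nonpolar, tolerance = 1e-9)
  expect_equal(pf$dG_nonpolar, 0.0072 * pf$dSASA, tolerance = 1e-9)
  expect_equal(pf$dG_binding, pf$dE_gas + pf$dG_solvation, tolerance = 1e-9)
  expect_error(binding_energy(tr, 1:3, 3:4, par), "overlap")
})

test_that("a two-particle host-guest toy equals the hand-built terms", {
  # fixed geometry: one receptor atom, one ligand atom at 4 A
  X <- rbind(c(0, 0, 0), c(4, 0, 0))
  tr <- toy_trajectory(matrix(as.numeric(t(X)), nrow = 1))
  par <- ff_params(c(0.5, -0.5), rstar = c(1.8, 1.6),
                   epsilon = c(0.15, 0.2), gb_radius = c(1.8, 1.6))
  dec <- binding_energy(tr, 1L, 2L, par, n_points = 960L,
                        solvent_dielectric = 80, offset = 0, scale = 0.8)
  pf <- dec$per_frame
  # hand terms
  ele <- 332.0636 * 0.5 * -0.5 / 4
  rm_ij <- 1.8 + 1.6; e_ij <- sqrt(0.15 * 0.2)
  vdw <- e_ij * ((rm_ij / 4)^12 - 2 * (rm_ij / 4)^6)
  alpha <- born_radii(X, par, offset = 0, scale = 0.8)
  gb_pair <- gb_energy(X, par, 80, 1, offset = 0, scale = 0.8)
  gb_self <- gb_energy(X[1, , drop = FALSE], par[1, ], 80, 1, offset = 0) +
    gb_energy(X[2, , drop = FALSE], par[2, ], 80, 1, offset = 0)
  sasa_c <- sasa(X, par$rstar, 1.4, 960)$total
  sasa_parts <- sasa(X[1, , drop = FALSE], par$rstar[1], 1.4, 960)$total +
    sasa(X[2, , drop = FALSE], par$rstar[2], 1.4, 960)$total
  np <- 0.0072 * (sasa_c - sasa_parts)
  expect_equal(pf$dE_ele, ele, tolerance = 1e-9)
  expect_equal(pf$dE_vdW, vdw, tolerance = 1e-9)
  expect_equal(pf$dG_GB, gb_pair - gb_self, tolerance = 1e-9)
  expect_equal(pf$dG_nonpolar, np, tolerance = 1e-9)
  expect_equal(pf$dG_binding, ele + vdw + (gb_pair - gb_self) + np,
               tolerance = 1e-9)
})

test_that("non-interacting ligands bind with essentially zero energy", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(500, 0, 0), c(503, 0, 0))
  tr <- toy_trajectory(matrix(as.numeric(t(ref)), nrow = 1))
  par <- ff_params(c(0, 0, 0, 0), 1.8, 0.1, 1.7)   # charges zeroed
  dec <- binding_energy(tr, 1:2, 3:4, par, n_points = 400L)
  expect_equal(dec$summary$mean[dec$summary$term == "dG_binding"], 0,
               tolerance = 1e-6)
})

test_that("binding energy is label- and frame-transform invariant", {
  set.seed(5)
  ref <- rbind(c(0, 0, 0), c(3.1, 0.4, 0), c(6.5, 0, 0.3), c(9.4, 0.5, 0))
  tr <- toy_trajectory(matrix(as.numeric(t(ref)), nrow = 1))
  par <- ff_params(c(0.3, -0.2, 0.4, -0.5), 1.8, 0.1, 1.7)
  d1 <- binding_energy(tr, 1:2, 3:4, par, n_points = 400L)
  d2 <- binding_energy(tr, 3:4, 1:2, par, n_points = 400L)
  expect_equal(d1$summary$mean[d1$summary$term == "dG_binding"],
               d2$summary$mean[d2$summary$term == "dG_binding"],
               tolerance = 1e-9)
  # rigid transform of the whole frame: analytic terms are exact, the
  # surface quadrature is invariant only up to its discretization error
  R <- random_rotation()
  moved <- sweep(ref %*% t(R), 2, c(10, -5, 3), "+")
  tr2 <- toy_trajectory(matrix(as.numeric(t(moved)), nrow = 1))
  d3 <- binding_energy(tr2, 1:2, 3:4, par, n_points = 400L)
  exact <- c("dE_ele", "dE_vdW", "dE_gas", "dG_GB")
  expect_equal(d1$summary$mean[match(exact, d1$summary$term)],
               d3$summary$mean[match(exact, d3$summary$term)],
               tolerance = 1e-9)
  expect_equal(d1$summary$mean[d1$summary$term == "dG_binding"],
               d3$summary$mean[d3$summary$term == "dG_binding"],
               tolerance = 0.05)
})

test_that("printed-table aggregation and state differences recompute exactly", {
  # assembling a table from per-term rows reproduces its total by summation
  unb <- energy_table(dE_ele = -1840.20, dE_vdW = -191.96, dG_GB = 1945.76,
                      dG_nonpolar = -30.76)
  total <- unb$summary$mean[unb$summary$term == "dG_binding"]
  expect_equal(total, -86.40, tolerance = 1e-9)
  bnd <- energy_table(dE_ele = -1650.34, dE_vdW = -190.76, dG_GB = 1728.12,
                      dG_nonpolar = -29.32)
  cmp <- aggregate_and_compare(bnd, unb)
  ddg <- cmp$diff[cmp$term == "dG_binding"]
  expect_equal(ddg, -112.98 - (-86.40), tolerance = 1e-9)
  # identical decompositions difference to zero
  cmp0 <- aggregate_and_compare(unb, unb)
  expect_true(all(cmp0$diff[!is.na(cmp0$diff)] == 0))
})
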