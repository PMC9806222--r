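# Independent oracles used to cross-check the package's implementations.
# These are deliberately written by a different route than the code under
# test (quaternions vs SVD, triple loops vs crossprod, enumeration vs
# iterative heuristics).

# Horn's quaternion method for optimal superposition RMSD.
quaternion_rmsd <- function(mobile, reference) {
  M <- if (is.matrix(mobile)) mobile else matrix(mobile, ncol = 3, byrow = TRUE)
  R <- if (is.matrix(reference)) reference else matrix(reference, ncol = 3, byrow = TRUE)
  Mc <- sweep(M, 2, colMeans(M))
  Rc <- sweep(R, 2, colMeans(R))
  S <- crossprod(Mc, Rc)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Mc^2) + sum(Rc^2) - 2 * lam) / nrow(M)
  sqrt(max(msd, 0))
}

# Brute-force DCCM by explicit triple loop over atoms and frames.
bruteforce_dccm <- function(xyz) {
  nf <- nrow(xyz); n <- ncol(xyz) / 3
  coords <- lapply(seq_len(nf), function(f) matrix(xyz[f, ], ncol = 3, byrow = TRUE))
  mean_pos <- Reduce(`+`, coords) / nf
  cv <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(nf)) {
      di <- coords[[f]][i, ] - mean_pos[i, ]
      dj <- coords[[f]][j, ] - mean_pos[j, ]
      s <- s + sum(di * dj)
    }
    cv[i, j] <- s / nf
  }
  d <- sqrt(diag(cv))
  cv / outer(d, d)
}

# All set partitions of n elements as membership vectors.
set_partitions <- function(n) {
  out <- list()
  rec <- function(mem, k) {
    i <- length(mem) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- mem; return(invisible()) }
    for (b in seq_len(k + 1L)) rec(c(mem, b), max(k, b))
  }
  rec(integer(0), 0L)
  out
}

# Newman-Girvan modularity of a membership vector on an unweighted edge list.
edge_modularity <- function(edges, membership) {
  m <- nrow(edges)
  nc <- max(membership)
  deg <- tabulate(c(edges$i, edges$j), length(membership))
  mi <- membership[edges$i]
  same <- mi == membership[edges$j]
  Lc <- tabulate(mi[same], nc)
  dc <- as.numeric(rowsum(deg, membership, reorder = TRUE))
  sum(Lc / m) - sum((dc / (2 * m))^2)
}

# Exhaustive maximum-modularity partition by enumerating all set partitions.
exhaustive_max_modularity <- function(edges, n) {
  parts <- set_partitions(n)
  best <- -Inf; best_mem <- NULL
  for (mem in parts) {
    q <- edge_modularity(edges, mem)
    if (q > best + 1e-12) { best <- q; best_mem <- mem }
  }
  list(modularity = best, membership = best_mem)
}

# Brute-force pairwise nonbonded energies.
bruteforce_coulomb <- function(X, q, pairs, eps = 1) {
  s <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    s <- s + 332.0636 * q[i] * q[j] / (eps * r)
  }
  s
}

bruteforce_lj <- function(X, rstar, eps, pairs) {
  s <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    rm <- rstar[i] + rstar[j]; e <- sqrt(eps[i] * eps[j])
    s <- s + e * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  s
}

# Independent evaluation of the pairwise generalized-Born sum for given
# effective radii.
oracle_gb <- function(X, q, alpha, eps_in = 1, eps_out = 80) {
  n <- nrow(X)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((X[i, ] - X[j, ])^2)
    f <- sqrt(r2 + alpha[i] * alpha[j] * exp(-r2 / (4 * alpha[i] * alpha[j])))
    tot <- tot + q[i] * q[j] / f
  }
  -0.5 * 332.0636 * (1 / eps_in - 1 / eps_out) * tot
}
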