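#' Per-atom force-field parameter table
#'
#' A minimal parameter container for the interaction-energy decomposition:
#' partial charge (e), Lennard-Jones R* (A, the distance at the pair
#' minimum is R*_i + R*_j) and well depth epsilon (kcal/mol, combined
#' geometrically), and an intrinsic generalized-Born radius (A). The
#' calcium entry shipped with [demo_ff_params()] uses R* = 1.79 A and
#' epsilon = 0.0140 kcal/mol, the ion parameters recorded in the pipeline
#' configuration metadata.
#'
#' @param charge Numeric vector of partial charges (e).
#' @param rstar Lennard-Jones R* per atom (A), > 0.
#' @param epsilon Well depths (kcal/mol), >= 0.
#' @param gb_radius Intrinsic Born radii (A), > 0.
#' @return A data frame of class `ff_params`.
#' @export
ff_params <- function(charge, rstar, epsilon, gb_radius) {
  n <- length(charge)
  rstar <- rep_len(rstar, n); epsilon <- rep_len(epsilon, n)
  gb_radius <- rep_len(gb_radius, n)
  stopifnot(all(is.finite(charge)), all(rstar > 0), all(epsilon >= 0),
            all(gb_radius > 0))
  structure(data.frame(charge = charge, rstar = rstar, epsilon = epsilon,
                       gb_radius = gb_radius),
            class = c("ff_params", "data.frame"))
}

#' Read/write a parameter table as delimited text
#' @param path File path; whitespace-delimited with a header line
#'   `charge rstar epsilon gb_radius`.
#' @return An `ff_params` table.
#' @export
read_ff_params <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  ff_params(d$charge, d$rstar, d$epsilon, d$gb_radius)
}

#' @rdname read_ff_params
#' @param params An `ff_params` table.
#' @export
write_ff_params <- function(params, path) {
  utils::write.table(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.pair_matrix <- function(pairs) {
  p <- as.matrix(pairs)
  stopifnot(ncol(p) == 2)
  storage.mode(p) <- "integer"
  p
}

.pair_dist <- function(X, p) {
  dv <- X[p[, 1], , drop = FALSE] - X[p[, 2], , drop = FALSE]
  sqrt(rowSums(dv^2))
}

#' Coulomb energy over an atom-pair set
#'
#' Sum of k_e q_i q_j / (eps_r r_ij) with k_e = 332.0636 kcal mol^-1 A e^-2.
#'
#' @param coords xyz vector or N x 3 matrix (A).
#' @param charges Partial charges (e), or an `ff_params` table.
#' @param pairs Two-column matrix of atom index pairs; default all i < j.
#' @param dielectric Relative dielectric (> 0), default 1.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, charges, pairs = NULL, dielectric = 1) {
  stopifnot(dielectric > 0)
  X <- .as_coord_matrix(coords)
  q <- if (inherits(charges, "ff_params")) charges$charge else as.numeric(charges)
  stopifnot(length(q) == nrow(X))
  p <- if (is.null(pairs)) t(utils::combn(nrow(X), 2)) else .pair_matrix(pairs)
  if (nrow(p) == 0L) return(0)
  r <- .pair_dist(X, p)
  if (any(r < 1e-8)) stop("coincident atoms in a Coulomb pair")
  sum(KE_COULOMB * q[p[, 1]] * q[p[, 2]] / (dielectric * r))
}

#' Lennard-Jones 12-6 energy over an atom-pair set
#'
#' Combination rules: R*_ij = R*_i + R*_j (arithmetic on the per-atom R*),
#' eps_ij = sqrt(eps_i eps_j). The pair minimum is exactly -eps_ij at
#' r = R*_ij.
#'
#' @param coords Coordinates.
#' @param params An `ff_params` table (uses `rstar`, `epsilon`).
#' @param pairs Two-column pair matrix; default all i < j.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(coords, params, pairs = NULL) {
  X <- .as_coord_matrix(coords)
  stopifnot(inherits(params, "ff_params"), nrow(params) == nrow(X))
  p <- if (is.null(pairs)) t(utils::combn(nrow(X), 2)) else .pair_matrix(pairs)
  if (nrow(p) == 0L) return(0)
  r <- .pair_dist(X, p)
  if (any(r < 1e-8)) stop("zero distance in a Lennard-Jones pair")
  rm_ij <- params$rstar[p[, 1]] + params$rstar[p[, 2]]
  eps_ij <- sqrt(params$epsilon[p[, 1]] * params$epsilon[p[, 2]])
  s6 <- (rm_ij / r)^6
  sum(eps_ij * (s6^2 - 2 * s6))
}

#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar style pairwise descreening: each atom's inverse
#' effective radius is its inverse intrinsic radius (minus `offset`)
#' reduced by an analytic integral over every other atom's scaled sphere.
#' An isolated atom's effective radius is exactly its (offset-corrected)
#' intrinsic radius, which anchors the analytic Born-ion limit.
#'
#' @param coords Coordinates.
#' @param gb_radius Intrinsic radii (A) or an `ff_params` table.
#' @param offset Radius offset (A), default 0.09 (set 0 for the textbook
#'   Born ion).
#' @param scale Descreening scale factor applied to neighbor radii,
#'   default 0.8.
#' @return Numeric vector of effective Born radii (A).
#' @export
born_radii <- function(coords, gb_radius, offset = 0.09, scale = 0.8) {
  X <- .as_coord_matrix(coords)
  R <- if (inherits(gb_radius, "ff_params")) gb_radius$gb_radius
       else as.numeric(gb_radius)
  stopifnot(length(R) == nrow(X))
  rho <- R - offset
  if (any(rho <= 0)) stop("offset leaves a nonpositive intrinsic radius")
  n <- nrow(X)
  inv_alpha <- 1 / rho
  if (n > 1) {
    for (i in seq_len(n)) {
      I <- 0
      for (j in seq_len(n)[-i]) {
        r <- sqrt(sum((X[i, ] - X[j, ])^2))
        sr <- scale * rho[j]
        if (r + sr <= rho[i]) next       # j fully inside i: no descreening
        L <- max(rho[i], abs(r - sr))
        U <- r + sr
        H <- 0.5 * ((1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
                      (1 / (2 * r)) * log(L / U) +
                      (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
        if (r < sr - rho[i]) H <- H + (1 / rho[i] - 1 / L)
        I <- I + H
      }
      inv_alpha[i] <- 1 / rho[i] - I
    }
  }
  if (any(inv_alpha <= 0))
    stop("nonpositive effective Born radius; geometry/radii are unphysical ",
         "for pairwise descreening")
  1 / inv_alpha
}

#' Generalized-Born polar solvation energy
#'
#' Pairwise generalized-Born energy
#' E = -1/2 k_e (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij), with
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))) and f_GB(i,i) = a_i,
#' the effective radii a coming from [born_radii()] unless supplied
#' directly. A single ion reduces to the Born self-energy
#' -1/2 (1/eps_in - 1/eps_out) k_e q^2 / a.
#'
#' @param coords Coordinates.
#' @param params An `ff_params` table (charges + intrinsic radii), or a
#'   numeric charge vector if `effective_radii` is given.
#' @param solvent_dielectric,solute_dielectric Dielectrics (> 0); defaults
#'   78.5 and 1.
#' @param effective_radii Optional precomputed effective Born radii.
#' @param offset,scale Passed to [born_radii()].
#' @return Energy in kcal/mol.
#' @export
gb_energy <- function(coords, params, solvent_dielectric = 78.5,
                      solute_dielectric = 1, effective_radii = NULL,
                      offset = 0.09, scale = 0.8) {
  stopifnot(solvent_dielectric > 0, solute_dielectric > 0)
  X <- .as_coord_matrix(coords)
  if (inherits(params, "ff_params")) {
    q <- params$charge
    alpha <- effective_radii %||% born_radii(X, params, offset, scale)
  } else {
    q <- as.numeric(params)
    if (is.null(effective_radii))
      stop("supply an ff_params table or explicit effective_radii")
    alpha <- effective_radii
  }
  stopifnot(length(q) == nrow(X), length(alpha) == nrow(X))
  if (any(alpha <= 0)) stop("nonpositive Born radius")
  pref <- -0.5 * KE_COULOMB * (1 / solute_dielectric - 1 / solvent_dielectric)
  e <- sum(q^2 / alpha)                        # self terms
  if (nrow(X) > 1) {
    p <- t(utils::combn(nrow(X), 2))
    r2 <- rowSums((X[p[, 1], , drop = FALSE] - X[p[, 2], , drop = FALSE])^2)
    aa <- alpha[p[, 1]] * alpha[p[, 2]]
    fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
    e <- e + 2 * sum(q[p[, 1]] * q[p[, 2]] / fgb)
  }
  pref * e
}

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point quadrature: each atom's solvent-accessible sphere (radius
#' r_i + probe) is sampled with a deterministic golden-spiral point set; a
#' point is accessible when outside every neighbor's accessible sphere.
#' Per-atom SASA is the accessible fraction times the sphere area.
#'
#' @param coords Coordinates.
#' @param radii Per-atom radii (A).
#' @param probe Probe radius (A), default 1.4 (water).
#' @param n_points Points per sphere (>= 100), default 960.
#' @return List: `total` (A^2), `per_atom` (numeric vector).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  stopifnot(probe >= 0, n_points >= 100)
  X <- .as_coord_matrix(coords)
  radii <- rep_len(as.numeric(radii), nrow(X))
  stopifnot(all(radii > 0))
  pts <- .sphere_points(as.integer(n_points))
  n <- nrow(X)
  ra <- radii + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    P <- sweep(pts * ra[i], 2, X[i, ], "+")
    acc <- rep(TRUE, nrow(P))
    for (j in seq_len(n)[-i]) {
      dij2 <- sum((X[i, ] - X[j, ])^2)
      if (dij2 >= (ra[i] + ra[j])^2) next     # spheres disjoint
      d2 <- (P[, 1] - X[j, 1])^2 + (P[, 2] - X[j, 2])^2 +
        (P[, 3] - X[j, 3])^2
      acc <- acc & d2 > ra[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * ra[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation energy from a surface-area change
#'
#' The linear surface-area model: Delta G_nonpolar = gamma * Delta SASA + b,
#' with the defaults gamma = 0.0072 kcal/(mol A^2) and b = 0.
#'
#' @param delta_sasa Surface-area change (A^2).
#' @param gamma Surface tension coefficient, kcal/(mol A^2).
#' @param b Intercept, kcal/mol.
#' @return Energy in kcal/mol.
#' @export
nonpolar_energy <- function(delta_sasa, gamma = 0.0072, b = 0) {
  gamma * delta_sasa + b
}
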