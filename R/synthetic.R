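#' Specification for a correlated Gaussian ensemble
#'
#' Describes an ensemble of particles fluctuating about fixed reference
#' coordinates with a prescribed residue-residue displacement correlation
#' matrix. Displacements are isotropic per particle: the same correlation
#' structure is applied independently to x, y and z, which makes the
#' displacement-vector correlation (the quantity the DCCM estimates) exactly
#' the target matrix.
#'
#' @param reference Reference coordinates: N x 3 matrix or xyz vector (A).
#' @param correlation N x N target correlation matrix: symmetric, unit
#'   diagonal, positive semi-definite, entries in [-1, 1].
#' @param amplitudes Per-particle fluctuation amplitudes (A), length 1 or N,
#'   all > 0.
#' @param n_frames Number of frames to draw.
#' @param seed Integer random seed; recorded in the output.
#' @return An `ensemble_spec` list, validated.
#' @export
ensemble_spec <- function(reference, correlation, amplitudes = 0.3,
                          n_frames = 1000L, seed = 1L) {
  ref <- .as_coord_matrix(reference)
  N <- nrow(ref)
  C <- as.matrix(correlation)
  if (nrow(C) != N || ncol(C) != N)
    stop("correlation matrix must be ", N, " x ", N)
  if (max(abs(C - t(C))) > 1e-10) stop("correlation matrix must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  if (max(abs(C)) > 1 + 1e-10)
    stop("correlation entries must lie in [-1, 1]")
  amplitudes <- rep_len(as.numeric(amplitudes), N)
  if (any(amplitudes <= 0)) stop("amplitudes must be > 0")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  stopifnot(n_frames >= 1)
  structure(list(reference = ref, correlation = C, amplitudes = amplitudes,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Symmetric PSD square root via eigendecomposition: C = V L V' -> V L^1/2 V'.
# This factorization is part of the generator contract (stable across
# versions); any square root reproduces the same ensemble statistics but not
# the same stream of frames.
.psd_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Generate a correlated Gaussian fluctuation ensemble
#'
#' Frames are independent draws of `reference + displacement`, where each
#' Cartesian axis of the displacement field is an independent N(0, Sigma)
#' draw with Sigma = diag(a) C diag(a). As the frame count grows, the
#' empirical displacement-vector correlation matrix converges to the target
#' at the usual 1/sqrt(frames) Monte-Carlo rate. Same spec + seed gives a
#' bit-identical trajectory. Frames carry no rigid-body diffusion: they are
#' already expressed in the reference frame.
#'
#' @param spec An [ensemble_spec()].
#' @param topology Optional `md_structure` to bind as topology; by default a
#'   minimal one-CA-per-residue topology is synthesized.
#' @return An `md_trajectory` with the seed recorded.
#' @export
generate_correlated_ensemble <- function(spec, topology = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  N <- nrow(spec$reference)
  S <- .psd_sqrt(spec$correlation)
  amp <- spec$amplitudes
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  nf <- spec$n_frames
  xyz <- matrix(0, nrow = nf, ncol = 3 * N)
  ref_flat <- as.numeric(t(spec$reference))
  for (f in seq_len(nf)) {
    Z <- matrix(rnorm(3 * N), nrow = N, ncol = 3)   # axis-wise std normal
    D <- (S %*% Z) * amp                            # correlated, scaled
    xyz[f, ] <- ref_flat + as.numeric(t(D))
  }
  topo <- topology %||% .ca_topology(spec$reference)
  new_md_trajectory(topo, xyz, source = "generate_correlated_ensemble",
                    seed = spec$seed)
}

# Minimal poly-alanine CA topology for synthetic particle systems.
.ca_topology <- function(ref) {
  N <- nrow(ref)
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(N), elety = "CA", alt = "",
    resid = "ALA", chain = "A", resno = seq_len(N), insert = "",
    x = ref[, 1], y = ref[, 2], z = ref[, 3],
    o = 1, b = 0, segid = "", elesy = "C", charge = "",
    stringsAsFactors = FALSE)
  new_md_structure(atom, source = "synthetic", format = "synthetic")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a two-substate conformational mixture
#'
#' Frames are drawn from a labeled mixture of two correlated Gaussian
#' ensembles sharing a particle count; the true state labels are attached
#' for downstream validation (clustering, landscape basin counts). The
#' mixture must be proper (0 < weightA < 1).
#'
#' @param specA,specB [ensemble_spec()]s with the same particle count.
#' @param weightA Probability that a frame comes from state A.
#' @param n_frames Total frames; defaults to `specA$n_frames`.
#' @param seed Seed for the mixture labels and the draws; defaults to
#'   `specA$seed`.
#' @return An `md_trajectory` with attribute `labels` (integer vector, 1 for
#'   state A frames, 2 for state B).
#' @export
generate_two_state_ensemble <- function(specA, specB, weightA = 0.5,
                                        n_frames = specA$n_frames,
                                        seed = specA$seed) {
  stopifnot(inherits(specA, "ensemble_spec"), inherits(specB, "ensemble_spec"))
  if (nrow(specA$reference) != nrow(specB$reference))
    stop("particle-count mismatch: ", nrow(specA$reference), " vs ",
         nrow(specB$reference))
  if (!(weightA > 0 && weightA < 1))
    stop("weightA must be strictly between 0 and 1 (a proper mixture)")
  N <- nrow(specA$reference)
  SA <- .psd_sqrt(specA$correlation); SB <- .psd_sqrt(specB$correlation)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  labels <- ifelse(runif(n_frames) < weightA, 1L, 2L)
  xyz <- matrix(0, nrow = n_frames, ncol = 3 * N)
  refA <- as.numeric(t(specA$reference)); refB <- as.numeric(t(specB$reference))
  for (f in seq_len(n_frames)) {
    Z <- matrix(rnorm(3 * N), nrow = N, ncol = 3)
    if (labels[f] == 1L) {
      xyz[f, ] <- refA + as.numeric(t((SA %*% Z) * specA$amplitudes))
    } else {
      xyz[f, ] <- refB + as.numeric(t((SB %*% Z) * specB$amplitudes))
    }
  }
  traj <- new_md_trajectory(.ca_topology(specA$reference), xyz,
                            source = "generate_two_state_ensemble",
                            seed = as.integer(seed))
  attr(traj, "labels") <- labels
  traj
}

#' Specification for an ion + solvation-shell toy system
#'
#' A fixed ion, a first coordination shell of `occupancy` particles at
#' radius `shell_radius` (jittered radially), and an ideal-gas bulk of
#' uniform number density filling the rest of an orthorhombic box. The bulk
#' has no excluded volume except a sphere around the shell, so its radial
#' distribution is analytically flat (g = 1).
#'
#' @param ion Ion position, length-3 (A); default box center.
#' @param shell_radius First-shell radius r0 (A).
#' @param occupancy Number of shell particles (>= 0).
#' @param box Orthorhombic box lengths, length-3 (A).
#' @param bulk_density Bulk particle number density (A^-3); 0 for no bulk.
#' @param jitter Radial jitter SD of shell particles (A).
#' @param n_frames Frames to draw.
#' @param seed Integer seed.
#' @return A `solvation_toy_spec` list, validated.
#' @export
solvation_toy_spec <- function(ion = NULL, shell_radius = 2.35,
                               occupancy = 7L, box = c(30, 30, 30),
                               bulk_density = 0.01, jitter = 0.05,
                               n_frames = 100L, seed = 1L) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  ion <- ion %||% (box / 2)
  stopifnot(length(ion) == 3)
  if (!(shell_radius < min(box) / 2))
    stop("shell radius must be smaller than half the minimum box dimension")
  stopifnot(occupancy >= 0, bulk_density >= 0, jitter >= 0, n_frames >= 1)
  structure(list(ion = as.numeric(ion), shell_radius = shell_radius,
                 occupancy = as.integer(occupancy), box = box,
                 bulk_density = bulk_density, jitter = jitter,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "solvation_toy_spec")
}

#' Generate an ion + solvation-shell toy trajectory
#'
#' Per frame: the ion is fixed; `occupancy` shell particles are placed at
#' `shell_radius` plus Gaussian radial jitter in uniformly random
#' directions; bulk particles are placed uniformly in the box, rejected
#' inside the shell exclusion sphere (radius r0 + max(0.5, 4 jitter)). The
#' bulk count is `round(density * box volume)`, so the bulk regime of g(r)
#' is 1 by construction. Placement failure after bounded retries (dense
#' systems) is an error.
#'
#' @param spec A [solvation_toy_spec()].
#' @return An `md_trajectory` whose topology is the ion (resname CAL) plus
#'   water oxygens (resname HOH, atom O); box stored in attribute `box`.
#' @export
generate_solvation_toy <- function(spec) {
  stopifnot(inherits(spec, "solvation_toy_spec"))
  r_excl <- spec$shell_radius + max(0.5, 4 * spec$jitter)
  n_bulk <- as.integer(round(spec$bulk_density * prod(spec$box)))
  n_part <- 1L + spec$occupancy + n_bulk
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  xyz <- matrix(0, nrow = spec$n_frames, ncol = 3 * n_part)
  for (f in seq_len(spec$n_frames)) {
    coords <- matrix(0, nrow = n_part, ncol = 3)
    coords[1, ] <- spec$ion
    if (spec$occupancy > 0) {
      u <- matrix(rnorm(3 * spec$occupancy), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- spec$shell_radius + rnorm(spec$occupancy, sd = spec$jitter)
      coords[1 + seq_len(spec$occupancy), ] <-
        sweep(u * r, 2, spec$ion, "+")
    }
    if (n_bulk > 0) {
      placed <- 0L; tries <- 0L; max_tries <- 200L
      pts <- matrix(0, nrow = n_bulk, ncol = 3)
      while (placed < n_bulk) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("bulk placement failed after ", max_tries,
               " retries; density too high for the exclusion volume")
        need <- n_bulk - placed
        cand <- cbind(runif(2 * need, 0, spec$box[1]),
                      runif(2 * need, 0, spec$box[2]),
                      runif(2 * need, 0, spec$box[3]))
        d2 <- rowSums(sweep(cand, 2, spec$ion)^2)
        ok <- cand[d2 > r_excl^2, , drop = FALSE]
        take <- min(nrow(ok), need)
        if (take > 0) {
          pts[placed + seq_len(take), ] <- ok[seq_len(take), , drop = FALSE]
          placed <- placed + take
        }
      }
      coords[1L + spec$occupancy + seq_len(n_bulk), ] <- pts
    }
    xyz[f, ] <- as.numeric(t(coords))
  }
  atom <- data.frame(
    type = c("HETATM", rep("HETATM", n_part - 1L)),
    eleno = seq_len(n_part),
    elety = c("CA", rep("O", n_part - 1L)), alt = "",
    resid = c("CAL", rep("HOH", n_part - 1L)), chain = "W",
    resno = seq_len(n_part), insert = "",
    x = 0, y = 0, z = 0, o = 1, b = 0, segid = "",
    elesy = c("CA", rep("O", n_part - 1L)), charge = "",
    stringsAsFactors = FALSE)
  first <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  atom$x <- first[, 1]; atom$y <- first[, 2]; atom$z <- first[, 3]
  topo <- new_md_structure(atom, source = "synthetic", format = "synthetic")
  traj <- new_md_trajectory(topo, xyz, source = "generate_solvation_toy",
                            seed = spec$seed)
  attr(traj, "box") <- spec$box
  attr(traj, "exclusion_radius") <- r_excl
  traj
}

#' Synthetic idealized EF-hand calcium binding site
#'
#' Builds, from ideal geometry, a stand-in for the second N-lobe EF-hand
#' calcium site of calmodulin: a Ca2+ ion in pentagonal-bipyramidal
#' sevenfold coordination by protein oxygens carrying the canonical EF-hand
#' ligand identities (sidechain Asp56, Asp58, Asn60, backbone Thr62,
#' sidechain Asp64 and a bidentate Glu67 carboxylate), with Ca-O distances
#' of 2.4 A. Non-coordinating backbone atoms of the loop are included so a
#' distance scan has something to exclude. This object is synthetic - an
#' idealized geometry, not deposited crystal coordinates - and is intended
#' for exercising [coordination_mode()] and related scans.
#'
#' @param ca_o Ca-O coordination distance in Angstrom (default 2.4).
#' @return An `md_structure` with one CA ion (resname CAL) and the loop
#'   atoms.
#' @export
synthetic_calcium_site <- function(ca_o = 2.4) {
  ion <- c(0, 0, 0)
  # pentagonal bipyramid: 5 equatorial + 2 axial vertices
  ang <- 2 * pi * (0:4) / 5
  eq <- cbind(cos(ang), sin(ang), 0)
  ax <- rbind(c(0, 0, 1), c(0, 0, -1))
  vert <- rbind(eq, ax) * ca_o
  lig <- data.frame(
    resid = c("ASP", "ASP", "ASN", "THR", "ASP", "GLU", "GLU"),
    resno = c(56L, 58L, 60L, 62L, 64L, 67L, 67L),
    elety = c("OD1", "OD1", "OD1", "O", "OD1", "OE1", "OE2"),
    stringsAsFactors = FALSE)
  # bidentate Glu67: bring its two oxygens closer together (axial pair is
  # 180 deg apart in the ideal polyhedron, unrealistic for one carboxylate);
  # put OE1/OE2 at two adjacent equatorial vertices instead and move the
  # displaced ligands to the axial spots.
  ligand_xyz <- vert[c(6, 7, 1, 2, 3, 4, 5), ]
  n_lig <- nrow(lig)
  # non-coordinating loop scaffold: CA and N atoms ~4-6 A away
  resnos <- c(56L, 58L, 60L, 62L, 64L, 67L)
  scaff <- do.call(rbind, lapply(seq_along(resnos), function(i) {
    th <- 2 * pi * i / length(resnos)
    base <- c(4.8 * cos(th), 4.8 * sin(th), 1.5 * (-1)^i)
    data.frame(resid = lig$resid[match(resnos[i], lig$resno)],
               resno = resnos[i],
               elety = c("N", "CA", "C"),
               x = base[1] + c(0, 0.8, 1.6),
               y = base[2] + c(0, 0.5, -0.3),
               z = base[3] + c(0, 0.4, 0.9),
               elesy = c("N", "C", "C"), stringsAsFactors = FALSE)
  }))
  atom <- data.frame(
    type = c("HETATM", rep("ATOM", n_lig + nrow(scaff))),
    eleno = seq_len(1L + n_lig + nrow(scaff)),
    elety = c("CA", lig$elety, scaff$elety), alt = "",
    resid = c("CAL", lig$resid, scaff$resid), chain = "B",
    resno = c(500L, lig$resno, scaff$resno), insert = "",
    x = c(ion[1], ligand_xyz[, 1], scaff$x),
    y = c(ion[2], ligand_xyz[, 2], scaff$y),
    z = c(ion[3], ligand_xyz[, 3], scaff$z),
    o = 1, b = 0, segid = "",
    elesy = c("CA", rep("O", n_lig), scaff$elesy), charge = "",
    stringsAsFactors = FALSE)
  new_md_structure(atom, source = "synthetic_calcium_site",
                   format = "synthetic")
}
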