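#' Dynamical cross-correlation matrix
#'
#' Computes the normalized covariance of atomic displacement vectors,
#' C_ij = c_ij / (c_ii^1/2 c_jj^1/2), with c_ij = <dr_i . dr_j> averaged
#' over frames and dr the full 3-vector displacement of an atom from its
#' ensemble-mean position. Positive values mean atoms i and j move in the
#' same direction; negative values mean anti-correlated motion.
#'
#' When a `reference` is supplied, every frame is first rigid-body fitted
#' to it on the selection: without that step any common rigid motion makes
#' all correlations 1 (see the package vignette). For synthetic ensembles
#' generated in a fixed frame (no rigid-body diffusion), pass
#' `reference = NULL`; superposition is then a statistical no-op in
#' principle but a biased estimator in practice, because it removes the
#' common-mode component of a correlated displacement field.
#'
#' Atoms with (numerically) zero positional variance cannot be normalized;
#' their rows and columns are flagged `NA` rather than divided by zero.
#'
#' @param traj An `md_trajectory` or list of replicas. A replica list is
#'   pooled; use `per_replica = TRUE` to also get the mean of per-replica
#'   matrices.
#' @param selection Atom indices / `atom_selection` (typically C-alpha).
#' @param reference Fitting reference (`md_structure`, xyz vector, or
#'   `NULL` for no fitting).
#' @param per_replica If `TRUE` and `traj` is a list, attach the average of
#'   per-replica DCCMs as attribute `per_replica_mean`.
#' @return A `correlation_matrix`: list with `C` (normalized, unit
#'   diagonal), `cov` (raw c_ij, A^2), `labels` (residue numbers of the
#'   selection when resolvable).
#' @export
dccm <- function(traj, selection, reference = NULL, per_replica = FALSE) {
  X <- .fitted_selection_coords(traj, selection, reference)
  if (nrow(X) < 2) stop("DCCM needs at least 2 frames")
  res <- .dccm_from_coords(X)
  trajs <- if (inherits(traj, "md_trajectory")) list(traj) else traj
  topo <- trajs[[1]]$topology
  idx <- as_atom_indices(selection, nrow(topo$atom))
  labels <- topo$atom$resno[idx]
  out <- structure(list(C = res$C, cov = res$cov, labels = labels),
                   class = "correlation_matrix")
  if (per_replica && length(trajs) > 1L) {
    mats <- lapply(trajs, function(tr)
      .dccm_from_coords(.fitted_selection_coords(tr, selection, reference))$C)
    attr(out, "per_replica_mean") <- Reduce(`+`, mats) / length(mats)
  }
  out
}

# Core arithmetic on a frames x 3n coordinate matrix: c_ij is the mean over
# frames of the displacement dot product, computed per axis by crossprod.
.dccm_from_coords <- function(X) {
  nf <- nrow(X)
  n <- ncol(X) / 3
  mu <- colMeans(X)
  D <- sweep(X, 2, mu)
  ix <- seq(1, 3 * n, by = 3)
  cv <- (crossprod(D[, ix, drop = FALSE]) +
         crossprod(D[, ix + 1, drop = FALSE]) +
         crossprod(D[, ix + 2, drop = FALSE])) / nf
  v <- diag(cv)
  zero <- v <= 1e-12        # A^2; far below any physical fluctuation
  s <- sqrt(ifelse(zero, NA_real_, v))
  C <- cv / outer(s, s)
  d <- diag(C)
  d[!zero] <- 1          # exactly 1 where the variance is positive
  diag(C) <- d
  list(C = C, cov = cv)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  n <- nrow(x$C)
  cat("correlation_matrix:", n, "x", n, "; range",
      sprintf("[%.3f, %.3f]\n", min(x$C, na.rm = TRUE), max(x$C, na.rm = TRUE)))
  invisible(x)
}

#' Mask weak correlations for display
#'
#' Entries with `|C_ij| < threshold` are replaced by `NA` (the mask
#' sentinel used by heat-map exports); the diagonal is always retained.
#' The comparison is strict, matching the usual "coefficients below the
#' cutoff are blanked" display rule, so an entry exactly at the threshold
#' survives.
#'
#' @param C A `correlation_matrix` or plain numeric matrix.
#' @param threshold Masking threshold in [0, 1], default 0.4.
#' @return Matrix of the same shape with masked entries `NA`.
#' @export
mask_dccm <- function(C, threshold = 0.4) {
  stopifnot(threshold >= 0, threshold <= 1)
  M <- if (inherits(C, "correlation_matrix")) C$C else as.matrix(C)
  out <- M
  out[abs(M) < threshold] <- NA_real_
  if (!is.null(dim(out))) diag(out) <- diag(M)
  out
}

#' Inter-domain correlation summary
#'
#' Statistics of the correlation sub-block between two disjoint residue
#' sets (e.g. kinase vs calmodulin): the mean correlation and the fraction
#' of pairs that are anti-correlated below a cutoff.
#'
#' @param C A `correlation_matrix` or numeric matrix.
#' @param blockA,blockB Disjoint, non-empty index sets (rows/columns of C).
#' @param anti_cutoff Pairs with `C < anti_cutoff` count as anti-correlated
#'   (default -0.4, mirroring the display-mask magnitude).
#' @return List: `mean` (mean C over the A x B block), `fraction_anti`,
#'   `n_pairs`.
#' @export
interdomain_summary <- function(C, blockA, blockB, anti_cutoff = -0.4) {
  M <- if (inherits(C, "correlation_matrix")) C$C else as.matrix(C)
  blockA <- as.integer(blockA); blockB <- as.integer(blockB)
  if (!length(blockA) || !length(blockB))
    stop("blocks must be non-empty")
  if (length(intersect(blockA, blockB)))
    stop("blocks overlap: ", paste(intersect(blockA, blockB), collapse = ", "))
  sub <- M[blockA, blockB, drop = FALSE]
  list(mean = mean(sub, na.rm = TRUE),
       fraction_anti = mean(sub < anti_cutoff, na.rm = TRUE),
       n_pairs = sum(!is.na(sub)))
}
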