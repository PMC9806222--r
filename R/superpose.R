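#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference coordinate set over a selection, by singular value
#' decomposition of the covariance of the centered coordinates. Reflections
#' are excluded by the usual determinant sign correction, so the rotation is
#' always proper (det = +1).
#'
#' @param mobile,reference Coordinates: a numeric xyz vector (x1,y1,z1,...)
#'   or an N x 3 matrix; both must have the same atom count.
#' @param selection Optional atom indices (or `atom_selection`) over which
#'   the fit is computed; defaults to all atoms. At least 3 non-collinear
#'   atoms are required.
#' @return A list of class `superposition`: `rotation` (3 x 3, proper),
#'   `translation` (length 3, Angstrom), `rmsd` (post-fit RMSD over the
#'   selection, Angstrom).
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(ref, ref)
#' fit$rmsd
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  M <- .as_coord_matrix(mobile)
  R <- .as_coord_matrix(reference)
  if (nrow(M) != nrow(R))
    stop("mobile and reference atom counts differ (", nrow(M), " vs ",
         nrow(R), ")")
  if (!is.null(selection)) {
    idx <- as_atom_indices(selection, nrow(M))
    M <- M[idx, , drop = FALSE]
    R <- R[idx, , drop = FALSE]
  }
  if (nrow(M) < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(M); cr <- colMeans(R)
  Mc <- sweep(M, 2, cm); Rc <- sweep(R, 2, cr)
  sv_ref <- svd(Rc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("degenerate (collinear) reference geometry; cannot superpose")
  H <- crossprod(Mc, Rc)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)       # maps centered mobile -> centered ref
  fitted <- Mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - Rc)^2)))
  trans <- as.numeric(cr - rot %*% cm)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords xyz vector or N x 3 matrix.
#' @param fit A `superposition`.
#' @return Transformed coordinates in the same shape as the input.
#' @export
apply_transform <- function(coords, fit) {
  vec_in <- !is.matrix(coords)
  X <- .as_coord_matrix(coords)
  Y <- X %*% t(fit$rotation)
  Y <- sweep(Y, 2, fit$translation, "+")
  if (vec_in) as.numeric(t(Y)) else Y
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b Coordinates (xyz vectors or N x 3 matrices) of equal size.
#' @param selection Optional atom indices.
#' @return RMSD in Angstrom (no fitting is performed; see
#'   [kabsch_superpose()] for the fitted value).
#' @export
coord_rmsd <- function(a, b, selection = NULL) {
  A <- .as_coord_matrix(a); B <- .as_coord_matrix(b)
  stopifnot(nrow(A) == nrow(B))
  if (!is.null(selection)) {
    idx <- as_atom_indices(selection, nrow(A))
    A <- A[idx, , drop = FALSE]; B <- B[idx, , drop = FALSE]
  }
  sqrt(mean(rowSums((A - B)^2)))
}

.as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) %% 3 == 0)
    matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  }
}

#' RMSD time series against a fixed reference
#'
#' Each frame is first rigid-body fitted to the reference on `fit_selection`
#' (Kabsch, geometric, no mass weighting), then the RMSD is evaluated on
#' `report_selection` (defaulting to the fit selection). Several replica
#' trajectories may be given as a list; frames are then pooled with equal
#' weight for the overall mean +/- SD and per-replica summaries are attached
#' as well, since ensemble papers rarely state which convention their
#' shaded-band figures use.
#'
#' @param traj An `md_trajectory` or a list of them (replicas).
#' @param reference An `md_structure` (or xyz vector matching the topology).
#' @param fit_selection Atom indices/`atom_selection` used for the fit.
#' @param report_selection Atom indices for the reported RMSD; default: the
#'   fit selection.
#' @param discard Number of initial frames to drop from each replica before
#'   analysis (equilibration discard; default 0).
#' @return A data frame of class `rmsd_series` with columns `replica`,
#'   `frame`, `rmsd`; attributes `mean`, `sd`, `per_replica` (data frame of
#'   per-replica means/SDs), `fit_label`, `report_label`.
#' @export
rmsd_series <- function(traj, reference, fit_selection,
                        report_selection = fit_selection, discard = 0L) {
  trajs <- if (inherits(traj, "md_trajectory")) list(traj) else traj
  stopifnot(length(trajs) >= 1)
  ref_xyz <- if (inherits(reference, "md_structure")) reference$xyz
             else as.numeric(reference)
  n <- length(ref_xyz) / 3
  fit_idx <- as_atom_indices(fit_selection, n, "fit selection")
  rep_idx <- as_atom_indices(report_selection, n, "report selection")
  refM <- .as_coord_matrix(ref_xyz)
  out <- vector("list", length(trajs))
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    stopifnot(inherits(tr, "md_trajectory"))
    frames <- seq_len(n_frames(tr))
    if (discard > 0L) frames <- frames[frames > discard]
    if (!length(frames)) stop("discard leaves no frames in replica ", r)
    vals <- vapply(frames, function(f) {
      M <- .as_coord_matrix(tr$xyz[f, ])
      fit <- kabsch_superpose(M, refM, fit_idx)
      fitted <- apply_transform(M, fit)
      coord_rmsd(fitted, refM, rep_idx)
    }, numeric(1))
    out[[r]] <- data.frame(replica = r, frame = frames, rmsd = vals)
  }
  df <- do.call(rbind, out)
  per_rep <- do.call(rbind, lapply(out, function(d) {
    data.frame(replica = d$replica[1], mean = mean(d$rmsd),
               sd = if (nrow(d) > 1) sd(d$rmsd) else 0)
  }))
  structure(df, class = c("rmsd_series", "data.frame"),
            mean = mean(df$rmsd),
            sd = if (nrow(df) > 1) sd(df$rmsd) else 0,
            per_replica = per_rep,
            fit_label = attr(fit_selection, "label", exact = TRUE),
            report_label = attr(report_selection, "label", exact = TRUE))
}

#' Summary statistics of an RMSD series
#' @param object An `rmsd_series`.
#' @param ... Ignored.
#' @return Named list with `mean`, `sd` (pooled over replicas) and
#'   `per_replica`.
#' @export
summary.rmsd_series <- function(object, ...) {
  list(mean = attr(object, "mean"), sd = attr(object, "sd"),
       per_replica = attr(object, "per_replica"))
}
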