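#' Pairwise post-superposition RMSD matrix over trajectory frames
#'
#' Entry (a, b) is the RMSD between frames a and b on the selection after
#' optimal rigid-body superposition of b onto a; the matrix is symmetric
#' with zero diagonal.
#'
#' @param traj An `md_trajectory`.
#' @param selection Atom indices / `atom_selection`.
#' @param stride Keep every `stride`-th frame (default 1).
#' @return Symmetric numeric matrix (A) with attribute `frames` (the frame
#'   indices used).
#' @export
pairwise_rmsd <- function(traj, selection, stride = 1L) {
  stopifnot(inherits(traj, "md_trajectory"), stride >= 1)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  idx <- as_atom_indices(selection, n_atoms(traj))
  coords <- lapply(frames, function(f)
    .as_coord_matrix(traj$xyz[f, ])[idx, , drop = FALSE])
  nfr <- length(frames)
  M <- matrix(0, nfr, nfr)
  for (a in seq_len(nfr - 1)) {
    for (b in seq((a + 1), nfr)) {
      M[a, b] <- M[b, a] <- kabsch_superpose(coords[[b]], coords[[a]])$rmsd
    }
  }
  attr(M, "frames") <- frames
  M
}

#' GROMOS-style neighbor-count clustering of a distance matrix
#'
#' Deterministic greedy clustering: the frame with the most neighbors
#' within `cutoff` seeds the first cluster (ties broken by lower frame
#' index), it and its neighbors are removed, and the procedure repeats on
#' the remainder. Every frame is assigned; cluster 1 is the most populated
#' by construction. The representative of each cluster is its medoid - the
#' member minimizing the summed distance to all other members (ties again
#' to the lower index).
#'
#' @param matrix Symmetric distance matrix with zero diagonal (e.g. from
#'   [pairwise_rmsd()]).
#' @param cutoff Neighbor cutoff in the matrix's units (default 2.0 A).
#' @return A `cluster_result`: `membership` (per frame), `populations`,
#'   `representatives` (medoid row index per cluster), `cutoff`.
#' @export
cluster_frames <- function(matrix, cutoff = 2.0) {
  M <- as.matrix(matrix)
  stopifnot(nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(M))) > 1e-8) stop("distance matrix must have zero diagonal")
  nfr <- nrow(M)
  membership <- integer(nfr)
  remaining <- seq_len(nfr)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    sub <- M[remaining, remaining, drop = FALSE]
    ncount <- rowSums(sub <= cutoff)        # includes self
    seed <- remaining[which.max(ncount)]    # which.max: lowest index on ties
    members <- remaining[sub[which.max(ncount), ] <= cutoff]
    membership[members] <- k
    remaining <- setdiff(remaining, members)
  }
  pops <- tabulate(membership, k)
  reps <- vapply(seq_len(k), function(cl) {
    mem <- which(membership == cl)
    if (length(mem) == 1L) return(mem)
    sums <- rowSums(M[mem, mem, drop = FALSE])
    mem[which.min(sums)]
  }, integer(1))
  structure(list(membership = membership, populations = pops,
                 representatives = reps, cutoff = cutoff,
                 frames = attr(matrix, "frames", exact = TRUE) %||%
                   seq_len(nfr)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$populations), "clusters; populations:",
      paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' Most representative structure of a trajectory
#'
#' Clusters the frames by pairwise RMSD and returns the medoid of the most
#' populated cluster as an `md_structure`.
#'
#' @param traj An `md_trajectory`.
#' @param selection Atom selection for the RMSD metric.
#' @param cutoff Cluster cutoff (A), default 2.0.
#' @param stride Frame stride for the pairwise matrix.
#' @return An `md_structure` with attributes `frame` (source frame index)
#'   and `cluster_result`.
#' @export
representative_structure <- function(traj, selection, cutoff = 2.0,
                                     stride = 1L) {
  M <- pairwise_rmsd(traj, selection, stride)
  cl <- cluster_frames(M, cutoff)
  top <- which.max(cl$populations)
  rep_row <- cl$representatives[top]
  frame <- cl$frames[rep_row]
  out <- frame_structure(traj, frame)
  attr(out, "frame") <- frame
  attr(out, "cluster_result") <- cl
  out
}

#' RMSD between two representative structures
#'
#' Superposes the shared selection of two models and reports the optimal
#' RMSD. Selections must map residue-to-residue: equal lengths and matching
#' residue numbers and atom names position by position; unmatched residues
#' are an error listing them.
#'
#' @param repA,repB `md_structure`s.
#' @param selectionA Atom selection in `repA`.
#' @param selectionB Atom selection in `repB`; default: the same indices.
#' @return RMSD in Angstrom.
#' @export
compare_representatives <- function(repA, repB, selectionA,
                                    selectionB = selectionA) {
  stopifnot(inherits(repA, "md_structure"), inherits(repB, "md_structure"))
  ia <- as_atom_indices(selectionA, nrow(repA$atom))
  ib <- as_atom_indices(selectionB, nrow(repB$atom))
  if (length(ia) != length(ib))
    stop("selections differ in size: ", length(ia), " vs ", length(ib))
  keyA <- paste(repA$atom$resno[ia], repA$atom$elety[ia])
  keyB <- paste(repB$atom$resno[ib], repB$atom$elety[ib])
  if (!all(keyA == keyB)) {
    bad <- which(keyA != keyB)
    stop("unmatched residues/atoms between the two models: ",
         paste(sprintf("%s != %s", keyA[bad], keyB[bad])[seq_len(min(5, length(bad)))],
               collapse = "; "))
  }
  A <- .as_coord_matrix(repA$xyz)[ia, , drop = FALSE]
  B <- .as_coord_matrix(repB$xyz)[ib, , drop = FALSE]
  kabsch_superpose(B, A)$rmsd
}
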