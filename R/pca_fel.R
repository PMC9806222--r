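#' Cartesian covariance principal component analysis
#'
#' Every frame is rigid-body fitted to the reference on the selection, the
#' 3N x 3N covariance matrix of the fitted selection coordinates is formed
#' about their ensemble mean, and diagonalized with a symmetric
#' eigensolver. Eigenvalues (A^2) come back sorted descending; eigenvector
#' signs are fixed by making each vector's largest-magnitude component
#' positive, so projections are reproducible. Replica lists are
#' concatenated after per-frame fitting to the shared reference.
#'
#' @param traj An `md_trajectory` or list of replicas.
#' @param selection Atom indices / `atom_selection` (>= 3 atoms).
#' @param reference `md_structure` or xyz vector; the fitting reference.
#'   `NULL` skips fitting (frames already share a common frame, as the
#'   synthetic generators produce).
#' @return A `pc_model`: `mean` (3n vector over the selection), `values`
#'   (eigenvalues, descending), `vectors` (orthonormal columns),
#'   `fractions` (variance fractions summing to 1), `selection`.
#' @export
covariance_pca <- function(traj, selection, reference = NULL) {
  X <- .fitted_selection_coords(traj, selection, reference)
  if (nrow(X) < 2) stop("PCA needs at least 2 frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # deterministic sign: largest-|component| positive
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(mean = mu, values = vals, vectors = vecs,
                 fractions = vals / sum(vals),
                 trace = sum(diag(cv)),
                 selection = as.integer(selection)),
            class = "pc_model")
}

# Frames x 3n matrix of (optionally fitted) selection coordinates; accepts
# a single trajectory or a replica list.
.fitted_selection_coords <- function(traj, selection, reference) {
  trajs <- if (inherits(traj, "md_trajectory")) list(traj) else traj
  n <- n_atoms(trajs[[1]])
  idx <- as_atom_indices(selection, n)
  cols <- xyz_indices(idx)
  ref_xyz <- if (is.null(reference)) NULL
             else if (inherits(reference, "md_structure")) reference$xyz
             else as.numeric(reference)
  blocks <- lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "md_trajectory"))
    if (is.null(ref_xyz)) return(tr$xyz[, cols, drop = FALSE])
    refM <- .as_coord_matrix(ref_xyz)
    t(vapply(seq_len(n_frames(tr)), function(f) {
      M <- .as_coord_matrix(tr$xyz[f, ])
      fit <- kabsch_superpose(M, refM, idx)
      as.numeric(t(apply_transform(M, fit)[idx, , drop = FALSE]))
    }, numeric(length(cols))))
  })
  do.call(rbind, blocks)
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", length(x$values), "modes; PC1+PC2 variance fraction",
      sprintf("%.3f", sum(x$fractions[1:2])), "\n")
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' Deviations of each (fitted) frame from the model mean are projected onto
#' the top-k eigenvectors. Projecting the mean structure itself gives the
#' origin; per-component projection variance equals the corresponding
#' eigenvalue (the defining PCA identity).
#'
#' @param traj An `md_trajectory` or replica list.
#' @param model A `pc_model`.
#' @param k Number of components (default 2).
#' @param reference Fitting reference (as in [covariance_pca()]); use the
#'   same choice that built the model.
#' @return Frames x k numeric matrix, columns `PC1..PCk`.
#' @export
project_frames <- function(traj, model, k = 2L, reference = NULL) {
  stopifnot(inherits(model, "pc_model"))
  if (k > ncol(model$vectors)) stop("k exceeds the number of eigenvectors")
  X <- .fitted_selection_coords(traj, model$selection, reference)
  if (ncol(X) != length(model$mean))
    stop("selection/model dimension mismatch: ", ncol(X), " vs ",
         length(model$mean))
  P <- sweep(X, 2, model$mean) %*% model$vectors[, seq_len(k), drop = FALSE]
  colnames(P) <- paste0("PC", seq_len(k))
  P
}

#' Free-energy surface from a density grid
#'
#' Boltzmann inversion of a sampled density: Delta G = -kB T ln(rho /
#' rho_max), kB = 0.0019872 kcal/(mol K). The most occupied bin is exactly
#' 0; unoccupied bins carry `NA` as the empty-bin sentinel. This is the
#' arithmetic core of [fel()]; it accepts any non-negative density grid.
#'
#' @param density Numeric matrix (or vector) of bin densities/counts >= 0.
#' @param temperature Temperature in K (> 0), default 300.
#' @return Object of class `fel_grid`: list with `energy` (same shape as
#'   `density`, kcal/mol), `temperature`, `kT`.
#' @export
fel_grid <- function(density, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  d <- as.array(density)
  if (any(d < 0, na.rm = TRUE)) stop("densities must be non-negative")
  dmax <- max(d, na.rm = TRUE)
  if (!(dmax > 0)) stop("at least one bin must be occupied")
  kT <- KB_KCALMOL * temperature
  g <- -kT * log(d / dmax)
  g[!is.finite(g)] <- NA_real_
  structure(list(energy = g, temperature = temperature, kT = kT),
            class = "fel_grid")
}

#' Free-energy landscape over two collective coordinates
#'
#' Histograms (PC1, PC2) projections on a regular grid and Boltzmann-inverts
#' the counts via [fel_grid()].
#'
#' @param projections Frames x >=2 matrix; first two columns are used.
#' @param temperature Kelvin, default 300 (the production-run temperature).
#' @param bins Number of bins per axis (length 1 or 2), default 80.
#' @param limits Optional list(x = c(lo, hi), y = c(lo, hi)); default spans
#'   the data extent, padded by half a bin.
#' @return A `fel_grid` with additional elements `x`, `y` (bin centers),
#'   `counts`.
#' @export
fel <- function(projections, temperature = 300, bins = 80, limits = NULL) {
  P <- as.matrix(projections)
  stopifnot(ncol(P) >= 2, nrow(P) >= 1)
  bins <- rep_len(as.integer(bins), 2)
  lim_x <- limits$x %||% range(P[, 1])
  lim_y <- limits$y %||% range(P[, 2])
  # widen degenerate ranges so a single point still occupies one bin
  if (diff(lim_x) == 0) lim_x <- lim_x + c(-0.5, 0.5)
  if (diff(lim_y) == 0) lim_y <- lim_y + c(-0.5, 0.5)
  ex <- seq(lim_x[1], lim_x[2], length.out = bins[1] + 1)
  ey <- seq(lim_y[1], lim_y[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(P[, 1], ex, rightmost.closed = TRUE), 1), bins[1])
  iy <- pmin(pmax(findInterval(P[, 2], ey, rightmost.closed = TRUE), 1), bins[2])
  counts <- matrix(0, bins[1], bins[2])
  for (f in seq_len(nrow(P))) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1
  out <- fel_grid(counts, temperature)
  out$x <- (ex[-1] + ex[-length(ex)]) / 2
  out$y <- (ey[-1] + ey[-length(ey)]) / 2
  out$counts <- counts
  out
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(!is.na(x$energy))
  cat(sprintf("fel_grid: %d occupied bins, relief %.2f kcal/mol at %g K\n",
              occ, max(x$energy, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Detect free-energy basins on a landscape grid
#'
#' Watershed/persistence flood-fill on the energy grid: occupied bins are
#' processed in order of increasing energy; a bin starts a new basin if none
#' of its 8-neighbors belongs to one yet, otherwise it joins (and possibly
#' merges) neighboring basins. When basins merge, the saddle level is the
#' current energy; a basin counts as a reported minimum only if its depth
#' below its separating saddle is at least `depth_threshold`. The deepest
#' basin always survives with depth equal to the grid relief.
#'
#' @param grid A `fel_grid` from [fel()].
#' @param depth_threshold Minimum depth (kcal/mol) below the separating
#'   saddle, default 0.5.
#' @return Data frame with one row per basin: `pc1`, `pc2` (bin centers of
#'   the basin minimum), `energy`, `depth`. Zero rows is possible only for
#'   an empty grid (never: one bin is always 0), so >= 1 row.
#' @export
basin_detect <- function(grid, depth_threshold = 0.5) {
  stopifnot(inherits(grid, "fel_grid"))
  E <- grid$energy
  nx <- nrow(E); ny <- ncol(E)
  occ <- which(!is.na(E))
  ord <- occ[order(E[occ])]
  basin <- matrix(NA_integer_, nx, ny)
  min_level <- numeric(0)     # basin minimum energy
  min_cell <- integer(0)      # linear index of basin minimum
  alive <- logical(0)         # still unmerged (or survived a merge)
  persist <- numeric(0)       # depth at which the basin died / survived
  root <- integer(0)          # union-find parent
  find <- function(i) { while (root[i] != i) i <- root[i]; i }
  for (cell in ord) {
    i <- (cell - 1) %% nx + 1; j <- (cell - 1) %/% nx + 1
    nb <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
          !is.na(basin[ii, jj]))
        nb <- c(nb, find(basin[ii, jj]))
    }
    nb <- unique(nb)
    if (length(nb) == 0L) {
      k <- length(min_level) + 1L
      min_level[k] <- E[cell]; min_cell[k] <- cell
      alive[k] <- TRUE; persist[k] <- NA_real_; root[k] <- k
      basin[i, j] <- k
    } else if (length(nb) == 1L) {
      basin[i, j] <- nb
    } else {
      # merge at saddle level E[cell]: keep the deepest, retire the rest
      lvls <- min_level[nb]
      keep <- nb[which.min(lvls)]
      for (b in setdiff(nb, keep)) {
        depth <- E[cell] - min_level[b]
        persist[b] <- depth
        alive[b] <- depth >= depth_threshold   # survived: deep enough
        root[b] <- keep
      }
      basin[i, j] <- keep
    }
  }
  # never-merged basins (including any disconnected occupied region) are
  # measured against the occupied-grid "sea level": empty bins act as
  # barriers at the top of the landscape
  sea <- max(E, na.rm = TRUE)
  root_ids <- which(root == seq_along(root))
  deepest_root <- root_ids[which.min(min_level[root_ids])]
  res <- lapply(seq_along(min_level), function(b) {
    never_merged <- root[b] == b
    depth <- if (never_merged) sea - min_level[b] else persist[b]
    # the deepest surviving basin is always reported; all others must clear
    # the threshold (absorbed basins by their merge depth, surviving ones
    # by their relief against the occupied-grid sea level)
    if (b != deepest_root &&
        ((never_merged && depth < depth_threshold) ||
         (!never_merged && !alive[b]))) return(NULL)
    cell <- min_cell[b]
    i <- (cell - 1) %% nx + 1; j <- (cell - 1) %/% nx + 1
    data.frame(pc1 = if (!is.null(grid$x)) grid$x[i] else i,
               pc2 = if (!is.null(grid$y)) grid$y[j] else j,
               energy = min_level[b], depth = depth)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out[order(out$energy), , drop = FALSE]
}
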