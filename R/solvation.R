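#' Radial pair distribution function with running coordination integral
#'
#' Histograms center-target distances over all frames and normalizes by the
#' exact spherical shell volume, the frame count, the center count and the
#' bulk number density, giving g(r); the running coordination integral
#' n(r) = rho * integral of 4 pi s^2 g(s) ds is computed from the raw
#' counts (so it is exact, not a quadrature of g). With box vectors
#' present, minimum-image distances are used (orthorhombic boxes).
#'
#' @param traj An `md_trajectory`.
#' @param center,target Atom selections (indices); e.g. an ion and water
#'   oxygens. Self-pairs (same atom index) are excluded.
#' @param bin_width Bin width in Angstrom (default 0.05).
#' @param r_max Histogram range (default 8 A); with a periodic box it must
#'   not exceed half the minimum box dimension.
#' @param box Orthorhombic box lengths (length 3) or `NULL`; defaults to
#'   the trajectory's `box` attribute if present.
#' @param density Bulk number density of the target species (A^-3);
#'   default: target count / box volume (requires a box).
#' @return An `rdf_profile` data frame: `r` (bin centers), `g`, `n`
#'   (running coordination number); attributes `density`, `bin_width`,
#'   `periodic`.
#' @export
rdf <- function(traj, center, target, bin_width = 0.05, r_max = 8,
                box = NULL, density = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), bin_width > 0, r_max > 0)
  n <- n_atoms(traj)
  ci <- as_atom_indices(center, n, "center selection")
  ti <- as_atom_indices(target, n, "target selection")
  box <- box %||% attr(traj, "box", exact = TRUE)
  periodic <- !is.null(box)
  if (periodic) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3)
    if (r_max > min(box) / 2 + 1e-9)
      stop("r_max exceeds half the minimum box dimension")
  }
  if (is.null(density)) {
    if (!periodic)
      stop("supply `density` or a periodic box to define the bulk density")
    density <- length(ti) / prod(box)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    X <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    for (c0 in ci) {
      tt <- setdiff(ti, c0)
      dv <- sweep(X[tt, , drop = FALSE], 2, X[c0, ])
      if (periodic) dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
      d <- sqrt(rowSums(dv^2))
      d <- d[d < r_max]
      if (length(d))
        counts <- counts + tabulate(pmin(floor(d / bin_width) + 1, nb), nb)
    }
  }
  norm <- nf * length(ci)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- counts / (norm * density * shell_vol)
  n_run <- cumsum(counts) / norm
  out <- data.frame(r = (edges[-1] + edges[-(nb + 1)]) / 2, g = g, n = n_run)
  structure(out, class = c("rdf_profile", "data.frame"),
            density = density, bin_width = bin_width, periodic = periodic,
            edges = edges)
}

#' Coordination number from an RDF profile
#'
#' Evaluates the running coordination integral n(r) at the first-minimum
#' cutoff. If no cutoff is given, the first local minimum of a smoothed
#' g(r) after the first substantial peak is detected; if that fails the
#' error advises an explicit cutoff.
#'
#' @param profile An `rdf_profile` from [rdf()].
#' @param first_minimum Cutoff radius in Angstrom, or `NULL` to detect.
#' @return Coordination number (real).
#' @export
coordination_number <- function(profile, first_minimum = NULL) {
  stopifnot(inherits(profile, "rdf_profile"))
  edges <- attr(profile, "edges")
  if (is.null(first_minimum)) {
    g <- as.numeric(stats::filter(profile$g, rep(1 / 5, 5), sides = 2))
    g[is.na(g)] <- profile$g[is.na(g)]
    pk <- which.max(g)
    if (!(g[pk] > 1.5))
      stop("no first-shell peak found; supply an explicit first_minimum cutoff")
    # walk downhill from the peak to the first local minimum
    i <- pk
    while (i < length(g) && g[i + 1] <= g[i]) i <- i + 1
    if (i >= length(g))
      stop("no first minimum found after the peak; supply an explicit cutoff")
    first_minimum <- profile$r[i]
  }
  if (first_minimum < edges[1] || first_minimum > edges[length(edges)])
    stop("first_minimum outside the profile range")
  # n is defined at the right bin edges; interpolate
  stats::approx(x = edges, y = c(0, profile$n), xout = first_minimum,
                rule = 2)$y
}

#' Coordination-mode catalogue for an ion site
#'
#' Lists every oxygen atom within `cutoff` of the ion, with its residue,
#' atom name and category: sidechain oxygen, backbone oxygen (carbonyl
#' O/OXT) or water oxygen. A bidentate carboxylate contributes two records.
#' The coordination number is the record count. An empty shell is a valid
#' (empty) result, not an error.
#'
#' @param structure An `md_structure` (e.g. a trajectory frame or a
#'   representative cluster structure).
#' @param ion Atom index of the ion (or a length-1 selection).
#' @param cutoff Coordination cutoff in Angstrom (default 3.0, roughly the
#'   first minimum of a Ca-O RDF).
#' @return A `coordination_shell`: list with `ligands` (data frame
#'   `resid`, `resno`, `chain`, `elety`, `category`, `distance`), `cn`,
#'   `ion` (row of the ion atom), `cutoff`.
#' @export
coordination_mode <- function(structure, ion, cutoff = 3.0) {
  stopifnot(inherits(structure, "md_structure"), cutoff > 0)
  a <- structure$atom
  ion <- as.integer(ion)
  if (length(ion) != 1L || ion < 1L || ion > nrow(a))
    stop("`ion` must be a single valid atom index")
  pos <- as.numeric(a[ion, c("x", "y", "z")])
  is_o <- toupper(trimws(a$elesy)) == "O" |
    (is.na(a$elesy) | a$elesy == "") & grepl("^O", a$elety)
  is_o[ion] <- FALSE
  d <- sqrt((a$x - pos[1])^2 + (a$y - pos[2])^2 + (a$z - pos[3])^2)
  sel <- which(is_o & d <= cutoff)
  cat_of <- function(i) {
    if (a$resid[i] %in% .WATER_RESNAMES) "water O"
    else if (a$elety[i] %in% c("O", "OXT")) "backbone O"
    else "sidechain O"
  }
  ligands <- data.frame(
    resid = a$resid[sel], resno = a$resno[sel], chain = a$chain[sel],
    elety = a$elety[sel],
    category = vapply(sel, cat_of, character(1)),
    distance = d[sel], stringsAsFactors = FALSE)
  ligands <- ligands[order(ligands$distance), , drop = FALSE]
  rownames(ligands) <- NULL
  structure(list(ligands = ligands, cn = nrow(ligands),
                 ion = a[ion, , drop = FALSE], cutoff = cutoff),
            class = "coordination_shell")
}

#' @export
print.coordination_shell <- function(x, ...) {
  cat("coordination_shell: CN =", x$cn, "within", x$cutoff, "A of",
      x$ion$resid, x$ion$resno, "\n")
  if (x$cn > 0) print(x$ligands)
  invisible(x)
}

#' Coordination-mode sensitivity sweep over the cutoff
#'
#' @param structure An `md_structure`.
#' @param ion Ion atom index.
#' @param cutoffs Cutoffs to scan (default 2.6 to 3.2 A).
#' @return Data frame `cutoff`, `cn`.
#' @export
coordination_sweep <- function(structure, ion, cutoffs = seq(2.6, 3.2, 0.1)) {
  data.frame(cutoff = cutoffs,
             cn = vapply(cutoffs, function(cc)
               coordination_mode(structure, ion, cc)$cn, numeric(1)))
}
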