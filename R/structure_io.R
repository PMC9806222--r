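#' Read a structure file into a structure model
#'
#' Parses a PDB file (via bio3d) into an `md_structure`: an ordered atom
#' table plus a flat coordinate vector in Angstrom. ATOM and HETATM records
#' are both kept, so crystallographic waters and ions are first-class atoms.
#' Alternate locations are collapsed to a single conformer: the
#' highest-occupancy altloc is retained, ties broken by altloc letter.
#' Residue numbering and insertion codes are preserved exactly as in the
#' source file.
#'
#' @param path Path to the file.
#' @param format File format; only `"pdb"` is supported.
#' @return An object of class `md_structure` with elements `atom` (data frame
#'   with bio3d-style columns `eleno`, `elety`, `alt`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`), `xyz` (numeric
#'   vector, length 3 * n_atoms), `source` and `format`.
#' @examples
#' pdb <- write_structure(synthetic_calcium_site(), tempfile(fileext = ".pdb"))
#' mod <- read_structure(pdb)
#' n_atoms(mod)
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, c("pdb"))
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse '", path, "' as PDB: ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L)
    stop("empty model: no ATOM/HETATM records in ", path)
  atom <- .apply_altloc_policy(atom)
  new_md_structure(atom, source = path, format = format)
}

new_md_structure <- function(atom, source = NA_character_, format = "pdb") {
  xyz <- as.numeric(t(as.matrix(atom[, c("x", "y", "z")])))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  structure(list(atom = atom, xyz = xyz, source = source, format = format),
            class = "md_structure")
}

# Keep one conformer per (chain, resno, insert, resid, elety): highest
# occupancy wins, ties broken by altloc letter (then file order).
.apply_altloc_policy <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  ord <- order(key, -occ, alt, seq_len(nrow(atom)))
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  atom[keep, , drop = FALSE]
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atom), "atoms,",
      length(unique(paste(x$atom$chain, x$atom$resno, x$atom$insert))),
      "residues\n")
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x An `md_structure` or `md_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$atom)
}

#' Write a structure model to a PDB file
#'
#' @param model An `md_structure`.
#' @param path Output path.
#' @param xyz Optional replacement coordinates (length 3 * n_atoms).
#' @return `path`, invisibly... returned visibly so it can be piped into
#'   [read_structure()].
#' @export
write_structure <- function(model, path, xyz = NULL) {
  stopifnot(inherits(model, "md_structure"))
  xyz <- xyz %||% model$xyz
  a <- model$atom
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = a$type %||% rep("ATOM", nrow(a)),
                   eleno = a$eleno, elety = a$elety, resid = a$resid,
                   chain = a$chain, resno = a$resno, insert = a$insert,
                   o = ifelse(is.na(a$o), 1, a$o),
                   b = ifelse(is.na(a$b), 0, a$b),
                   elesy = a$elesy)
  path
}

#' Read a coordinate trajectory bound to a topology
#'
#' Supported containers: multi-model PDB (`MODEL`/`ENDMDL` blocks, plain
#' text) and binary DCD. The frame atom count must equal the topology's;
#' a mismatch is an error stating both counts. A multi-model PDB whose last
#' `MODEL` block is not closed by `ENDMDL` is treated as truncated and the
#' error names the last complete frame.
#'
#' @param path Trajectory file.
#' @param topology An `md_structure` giving atom identities.
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @return An `md_trajectory`: list with `topology`, `xyz` (frames x 3N
#'   matrix), optional `time` (ns) and `source`.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "dcd")) {
  stopifnot(inherits(topology, "md_structure"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd",
                     xtc = stop("XTC trajectories are not supported; ",
                                "convert to DCD or multi-model PDB"),
                     stop("cannot infer trajectory format from extension '",
                          ext, "'"))
  }
  if (format == "pdb") {
    lines <- readLines(path)
    n_open <- sum(startsWith(lines, "MODEL"))
    n_close <- sum(startsWith(lines, "ENDMDL"))
    if (n_open > n_close)
      stop("truncated trajectory '", path, "': last complete frame is ",
           n_close, " (frame ", n_open, " has no ENDMDL)")
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            rm.alt = FALSE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  }
  n_top <- n_atoms(topology)
  n_trj <- ncol(xyz) / 3
  if (n_trj != n_top)
    stop("atom-count mismatch: trajectory has ", n_trj,
         " atoms but topology has ", n_top)
  new_md_trajectory(topology, xyz, source = path)
}

new_md_trajectory <- function(topology, xyz, time = NULL,
                              source = NA_character_, seed = NULL) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3 * n_atoms(topology), nrow(xyz) >= 1)
  structure(list(topology = topology, xyz = xyz, time = time,
                 source = source, seed = seed),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", nrow(x$xyz), "frames x", n_atoms(x$topology),
      "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Write a trajectory as a multi-model PDB
#'
#' Plain-text container readable by [read_trajectory()]; each frame becomes
#' one `MODEL`/`ENDMDL` block. The generator seed, when recorded on the
#' trajectory, is written as a REMARK so output provenance survives the
#' round trip.
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$topology$atom
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$seed))
    writeLines(sprintf("REMARK   7 GENERATOR SEED %d", as.integer(traj$seed)),
               con)
  type <- a$type %||% rep("ATOM", nrow(a))
  type <- format(type, width = 6)
  for (f in seq_len(nrow(traj$xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    recs <- sprintf("%s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    type, a$eleno %% 100000L,
                    .pdb_atom_name(a$elety), " ",
                    substr(a$resid, 1, 4),
                    ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
                    a$resno %% 10000L,
                    ifelse(is.na(a$insert) | a$insert == "", " ", a$insert),
                    xyz[, 1], xyz[, 2], xyz[, 3],
                    ifelse(is.na(a$o), 1, a$o), ifelse(is.na(a$b), 0, a$b),
                    ifelse(is.na(a$elesy), "", a$elesy))
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# PDB columns 13-16: element symbols of 1 char start in column 14.
.pdb_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", formatC(name, width = -3)))
}

#' Extract one frame of a trajectory as a structure model
#' @param traj An `md_trajectory`.
#' @param frame Frame index (1-based).
#' @return An `md_structure` with the frame's coordinates.
#' @export
frame_structure <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  a <- traj$topology$atom
  xyz <- matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new_md_structure(a, source = traj$source, format = "frame")
}
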