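#' Resolve an atom selection expression
#'
#' Selections use a small documented grammar. An expression is one or more
#' clauses joined by `and`; an atom must satisfy every clause. Each clause is
#' a keyword followed by one or more values (values within a clause are
#' alternatives):
#'
#' * `name <atom names>` - atom names, e.g. `name CA`, `name OD1 OD2`
#' * `resno <numbers/ranges>` - residue numbers, e.g. `resno 1:75 85:148`
#' * `resname <residue names>` - e.g. `resname ASP GLU`
#' * `chain <chain ids>` - e.g. `chain A`
#' * `element <element symbols>` - e.g. `element O`
#' * `water` - water residues (HOH/WAT/TIP3/SPC/SOL)
#' * `protein` - standard amino-acid residues
#' * `ion` - single-atom HETATM residues (CA/NA/CL/MG/ZN/K ions)
#' * `calpha` - shorthand for `protein and name CA`
#' * `noh` - exclude hydrogens
#' * `all` - every atom
#'
#' Selections are deterministic and order-preserving: indices come back in
#' file order, unique and ascending. An empty result is allowed but
#' signalled with a warning. Unknown chain or residue-name values are an
#' error listing what is available, which catches typos early.
#'
#' @param model An `md_structure` (or `md_trajectory`, whose topology is
#'   used).
#' @param expression Selection string.
#' @param label Optional human-readable label (defaults to the expression).
#' @return Integer vector of atom indices (class `atom_selection`) with
#'   attributes `expression` and `label`.
#' @examples
#' site <- synthetic_calcium_site()
#' select_atoms(site, "element O and resname ASP")
#' @export
select_atoms <- function(model, expression, label = expression) {
  if (inherits(model, "md_trajectory")) model <- model$topology
  stopifnot(inherits(model, "md_structure"), is.character(expression),
            length(expression) == 1L, nzchar(expression))
  a <- model$atom
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(a))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    vals <- toks[-1]
    keep <- keep & .eval_clause(a, kw, vals, cl)
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    warning("selection '", expression, "' matched no atoms")
  structure(idx, class = "atom_selection",
            expression = expression, label = label)
}

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL", "H2O")
.ION_RESNAMES <- c("CA", "NA", "CL", "MG", "ZN", "K", "CAL", "SOD", "CLA")
.AA_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.eval_clause <- function(a, kw, vals, clause) {
  need_vals <- function() {
    if (length(vals) == 0L)
      stop("selection clause '", clause, "' needs at least one value")
  }
  switch(kw,
    all = rep(TRUE, nrow(a)),
    name = { need_vals(); a$elety %in% vals },
    resname = {
      need_vals()
      avail <- unique(a$resid)
      bad <- setdiff(vals, avail)
      if (length(bad))
        stop("unknown residue name(s) ", paste(bad, collapse = ", "),
             "; available: ", paste(sort(avail), collapse = ", "))
      a$resid %in% vals
    },
    resno = {
      need_vals()
      nums <- unlist(lapply(vals, .parse_range))
      a$resno %in% nums
    },
    chain = {
      need_vals()
      avail <- unique(a$chain[!is.na(a$chain)])
      bad <- setdiff(vals, avail)
      if (length(bad))
        stop("unknown chain(s) ", paste(bad, collapse = ", "),
             "; available: ", paste(sort(avail), collapse = ", "))
      a$chain %in% vals
    },
    element = { need_vals(); toupper(trimws(a$elesy)) %in% toupper(vals) },
    water = a$resid %in% .WATER_RESNAMES,
    protein = a$resid %in% .AA_RESNAMES,
    ion = a$resid %in% .ION_RESNAMES & !(a$resid %in% .AA_RESNAMES),
    calpha = a$resid %in% .AA_RESNAMES & a$elety == "CA",
    noh = !(toupper(trimws(a$elesy)) %in% "H") &
      !grepl("^[0-9]*H", a$elety),
    stop("unknown selection keyword '", kw, "' in clause '", clause, "'")
  )
}

.parse_range <- function(tok) {
  if (grepl("^-?[0-9]+[:-][0-9-]+$", tok) && grepl("[:-]", sub("^-", "", tok))) {
    parts <- strsplit(sub("^(-?[0-9]+)[:-]", "\\1 ", tok), " ")[[1]]
    seq(as.integer(parts[1]), as.integer(parts[2]))
  } else {
    v <- suppressWarnings(as.integer(tok))
    if (is.na(v)) stop("cannot parse residue number token '", tok, "'")
    v
  }
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection '", attr(x, "label"), "': ", length(x), " atoms\n",
      sep = "")
  invisible(x)
}

# Accept either an atom_selection or a plain index vector; validate range.
as_atom_indices <- function(selection, n, what = "selection") {
  idx <- as.integer(selection)
  if (length(idx) == 0L) stop("empty ", what)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n))
    stop(what, " contains out-of-range atom indices")
  if (is.unsorted(idx, strictly = TRUE)) idx <- sort(unique(idx))
  idx
}

# xyz-vector indices (x,y,z triplets) for a set of atom indices.
xyz_indices <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}
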