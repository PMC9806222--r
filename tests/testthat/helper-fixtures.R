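# Fixtures are built in code at test time: small PDB texts, toy
# trajectories on minimal topologies, and hand-made contact graphs.

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, ele = substr(name, 1, 1),
                     record = "ATOM", alt = " ") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
    paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, " ", x, y, z, occ, b, ele)
}

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Three-atom fixture.
three_atom_pdb <- function() {
  write_tiny_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, ele = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, ele = "C"),
    pdb_line(3, "C", "ALA", "A", 1, 2.2, 1.2, 0, ele = "C")))
}

# Two-residue peptide with CA atoms plus 5 waters.
peptide_waters_pdb <- function() {
  lines <- c(
    pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0, ele = "N"),
    pdb_line(2, "CA", "GLY", "A", 1, 1.5, 0, 0, ele = "C"),
    pdb_line(3, "C", "GLY", "A", 1, 2.2, 1.2, 0, ele = "C"),
    pdb_line(4, "N", "ALA", "A", 2, 3.5, 1.3, 0, ele = "N"),
    pdb_line(5, "CA", "ALA", "A", 2, 4.4, 2.4, 0, ele = "C"),
    pdb_line(6, "C", "ALA", "A", 2, 5.8, 2.0, 0, ele = "C"))
  for (w in 1:5)
    lines <- c(lines, pdb_line(6 + w, "O", "HOH", "W", 100 + w,
                               10 + w, 5, 3, ele = "O", record = "HETATM"))
  write_tiny_pdb(lines)
}

# Calmodulin-linker-like gap: CA-only chain with residues 60..95 but
# 74-84 missing.
gapped_chain_pdb <- function() {
  resnos <- setdiff(60:95, 74:84)
  lines <- vapply(seq_along(resnos), function(k)
    pdb_line(k, "CA", "ALA", "A", resnos[k], 3.8 * k, 0, 0, ele = "C"),
    character(1))
  write_tiny_pdb(lines)
}

# Altloc fixture: one atom in two conformers plus a normal atom.
altloc_pdb <- function(occ_a = 0.6, occ_b = 0.4) {
  write_tiny_pdb(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = occ_a, alt = "A", ele = "C"),
    pdb_line(2, "CA", "SER", "A", 1, 0.5, 0, 0, occ = occ_b, alt = "B", ele = "C"),
    pdb_line(3, "CB", "SER", "A", 1, 1.5, 0, 0, ele = "C")))
}

# Trajectory from an explicit frames x 3N coordinate matrix on a CA-only
# topology (optionally a custom topology).
toy_trajectory <- function(xyz, topology = NULL) {
  xyz <- as.matrix(xyz)
  topo <- topology %||% mdensemble:::.ca_topology(
    matrix(xyz[1, ], ncol = 3, byrow = TRUE))
  mdensemble:::new_md_trajectory(topo, xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contact graph from an explicit edge data frame (i, j, persistence).
toy_graph <- function(edges, n_nodes = max(edges$i, edges$j),
                      cutoff = 4.5, threshold = 0.75) {
  structure(list(
    nodes = data.frame(node = seq_len(n_nodes), chain = "A",
                       resno = seq(1, by = 5, length.out = n_nodes)),
    edges = edges[order(edges$i, edges$j), , drop = FALSE],
    cutoff = cutoff, threshold = threshold),
    class = "contact_graph")
}

clique_edges <- function(nodes) {
  e <- t(combn(nodes, 2))
  data.frame(i = e[, 1], j = e[, 2], persistence = 1)
}

# Random orthonormal proper rotation.
random_rotation <- function() {
  repeat {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    if (abs(det(R) - 1) < 1e-8) return(R)
  }
}
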