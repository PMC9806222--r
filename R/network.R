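#' Persistence-filtered residue contact graph
#'
#' One node per residue (indexed at its C-alpha); an edge joins residues i
#' and j when any heavy-atom pair of the two residues lies within `cutoff`
#' in a strictly greater fraction of frames than `threshold`. The defaults
#' are the standard dynamic-network criterion: 4.5 A for more than 75% of
#' the trajectory. Sequence neighbors (|i-j| <= 1 on the same chain) are
#' excluded, otherwise trivial backbone contacts dominate edge
#' betweenness. The heavy-atom criterion (rather than C-alpha/C-alpha at
#' 4.5 A, which would disconnect the graph) follows the network-analysis
#' literature this construction comes from.
#'
#' @param traj An `md_trajectory`.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @param threshold Persistence fraction; an edge needs persistence
#'   strictly greater than this (default 0.75).
#' @param residues Optional selection restricting which atoms participate;
#'   default: all non-water heavy atoms.
#' @return A `contact_graph`: list with `nodes` (data frame `node`, `chain`,
#'   `resno`), `edges` (data frame `i`, `j`, `persistence`), `cutoff`,
#'   `threshold`.
#' @export
contact_persistence <- function(traj, cutoff = 4.5, threshold = 0.75,
                                residues = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0,
            threshold >= 0, threshold < 1)
  a <- traj$topology$atom
  keep <- !(a$resid %in% .WATER_RESNAMES) &
    !(toupper(trimws(a$elesy)) %in% "H") & !grepl("^[0-9]*H", a$elety)
  if (!is.null(residues))
    keep <- keep & seq_len(nrow(a)) %in% as.integer(residues)
  idx <- which(keep)
  if (!length(idx)) stop("no heavy atoms selected for the contact graph")
  rkey <- paste(a$chain[idx], a$resno[idx], a$insert[idx], sep = "|")
  rfac <- factor(rkey, levels = unique(rkey))
  nres <- nlevels(rfac)
  ratom <- as.integer(rfac)                 # residue id per kept atom
  nodes <- data.frame(node = seq_len(nres),
                      chain = a$chain[idx][!duplicated(ratom)],
                      resno = a$resno[idx][!duplicated(ratom)])
  nf <- n_frames(traj)
  counts <- matrix(0L, nres, nres)
  cols <- xyz_indices(idx)
  B <- matrix(0, length(ratom), nres)     # atom -> residue indicator
  B[cbind(seq_along(ratom), ratom)] <- 1
  for (f in seq_len(nf)) {
    X <- matrix(traj$xyz[f, cols], ncol = 3, byrow = TRUE)
    d <- as.matrix(stats::dist(X)) < cutoff
    # residue-pair contact: any heavy-atom pair within cutoff
    hit <- crossprod(B, d %*% B) > 0
    counts <- counts + hit
  }
  pers <- counts / nf
  same_chain <- outer(nodes$chain, nodes$chain, `==`)
  neighbor <- abs(outer(nodes$resno, nodes$resno, `-`)) <= 1 & same_chain
  ut <- upper.tri(pers)
  sel <- ut & pers > threshold & !neighbor
  ij <- which(sel, arr.ind = TRUE)
  edges <- data.frame(i = ij[, 1], j = ij[, 2],
                      persistence = pers[sel])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff,
                 threshold = threshold),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("contact_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      sprintf("edges (cutoff %.2f A, persistence > %.2f)\n",
              x$cutoff, x$threshold))
  invisible(x)
}

#' Weight contact-graph edges by correlation-derived distances
#'
#' Sets the edge distance D_ij = -ln|C_ij|: perfectly coupled residues are
#' zero-distance, weak coupling is far. The absolute value makes strongly
#' anti-correlated pairs "close" too and keeps D non-negative (the formula
#' is undefined for negative C otherwise); the natural logarithm is the
#' convention of the dynamical-network literature (any base only rescales
#' distances and leaves betweenness orderings unchanged). Edges whose
#' correlation is exactly 0 would be infinitely far and are dropped with a
#' warning.
#'
#' @param graph A `contact_graph` whose node order matches the rows of `C`.
#' @param C A `correlation_matrix` or numeric matrix over the graph nodes.
#' @return The graph with an added edge column `distance`.
#' @export
weight_edges <- function(graph, C) {
  stopifnot(inherits(graph, "contact_graph"))
  M <- if (inherits(C, "correlation_matrix")) C$C else as.matrix(C)
  if (nrow(M) != nrow(graph$nodes))
    stop("correlation matrix size (", nrow(M),
         ") does not match node count (", nrow(graph$nodes), ")")
  cij <- M[cbind(graph$edges$i, graph$edges$j)]
  if (any(abs(cij) > 1 + 1e-12, na.rm = TRUE))
    stop("|C_ij| > 1 on an edge; upstream correlation matrix is invalid")
  drop <- !is.na(cij) & cij == 0
  if (any(drop)) {
    warning(sum(drop), " edge(s) with C_ij = 0 dropped (infinite distance)")
    graph$edges <- graph$edges[!drop, , drop = FALSE]
    cij <- cij[!drop]
  }
  graph$edges$distance <- -log(pmin(abs(cij), 1))
  graph
}

# igraph view of a contact graph (named vertices "1".."n").
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$i),
               to = as.character(graph$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$node)))
  if (!is.null(graph$edges$distance))
    igraph::E(g)$distance <- graph$edges$distance
  igraph::E(g)$persistence <- graph$edges$persistence
  g
}

#' Girvan-Newman community decomposition
#'
#' Iteratively removes the edge of maximum betweenness (shortest-path edge
#' betweenness; when the graph carries -ln|C| distances and
#' `use_weights = TRUE` these are used as path lengths), recomputing after
#' every removal, and tracks the connected-component partition along the
#' way. The reported partition is the one of maximum Newman-Girvan
#' modularity, evaluated on the original (unweighted) graph. Ties in the
#' maximum betweenness are broken by lexicographic edge id (smallest i,
#' then j) so the decomposition is deterministic; equal-modularity
#' partitions resolve to the earliest (coarsest) one. Communities smaller
#' than `min_size` are omitted from the reported partition (membership
#' `NA`), following the usual "communities with fewer than three residues
#' are dropped" pruning.
#'
#' @param graph A `contact_graph` (weighted or not).
#' @param min_size Smallest reported community (default 3).
#' @param use_weights Use edge distances for betweenness when available
#'   (default TRUE).
#' @return A `community_partition`: list with `membership` (full, integer
#'   per node), `reported` (membership with small communities `NA`),
#'   `sizes` (table over reported communities), `modularity`, `min_size`.
#' @export
girvan_newman <- function(graph, min_size = 3L, use_weights = TRUE) {
  stopifnot(inherits(graph, "contact_graph"))
  if (nrow(graph$edges) == 0L) stop("graph has no edges")
  g0 <- as_igraph(graph)
  g <- g0
  best_mod <- -Inf
  best_mem <- .component_membership(g0)
  m0 <- igraph::modularity(g0, best_mem)
  best_mod <- m0
  while (igraph::ecount(g) > 0) {
    w <- if (use_weights && !is.null(igraph::E(g)$distance))
      igraph::E(g)$distance else NULL
    eb <- igraph::edge_betweenness(g, weights = w)
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-9 * max(mx, 1))
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, igraph::E(g)[cand])
      ij <- t(apply(matrix(as.integer(ends), ncol = 2), 1, sort))
      cand <- cand[order(ij[, 1], ij[, 2])]
    }
    g <- igraph::delete_edges(g, cand[1])
    mem <- .component_membership(g)
    mod <- igraph::modularity(g0, mem)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  membership <- as.integer(best_mem)
  sizes <- table(membership)
  small <- as.integer(names(sizes)[sizes < min_size])
  reported <- membership
  reported[reported %in% small] <- NA_integer_
  # renumber reported communities consecutively by first appearance
  reported <- as.integer(factor(reported, levels = unique(stats::na.omit(reported))))
  structure(list(membership = membership, reported = reported,
                 sizes = table(reported), modularity = best_mod,
                 min_size = as.integer(min_size)),
            class = "community_partition")
}

.component_membership <- function(g) {
  comp <- igraph::components(g)$membership
  comp[order(as.integer(names(comp)))]
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(x$sizes), "communities (size >=",
      x$min_size, "), modularity", sprintf("%.4f\n", x$modularity))
  invisible(x)
}

#' Difference contact network between two conformational states
#'
#' Maps a second state's contact graph onto the community partition
#' computed for the first state (the communities are held fixed, so the
#' comparison uses one community set) and reports the signed change in
#' inter-community connection strength. The strength between communities
#' (a, b) is the summed contact persistence of edges joining them; the
#' change is strength(B) - strength(A), so a pair whose contacts weaken in
#' state B is negative. The result is antisymmetric under swapping the
#' states.
#'
#' @param graphA `contact_graph` of the anchor state.
#' @param partition `community_partition` computed on `graphA`.
#' @param graphB `contact_graph` of the comparison state; must share the
#'   node universe with `graphA`.
#' @return A `difference_network`: list with `change` (symmetric matrix over
#'   reported communities, B minus A), `strengthA`, `strengthB`.
#' @export
difference_network <- function(graphA, partition, graphB) {
  stopifnot(inherits(graphA, "contact_graph"),
            inherits(partition, "community_partition"),
            inherits(graphB, "contact_graph"))
  keyA <- paste(graphA$nodes$chain, graphA$nodes$resno)
  keyB <- paste(graphB$nodes$chain, graphB$nodes$resno)
  if (!identical(sort(keyA), sort(keyB))) {
    missing_in_b <- setdiff(keyA, keyB)
    missing_in_a <- setdiff(keyB, keyA)
    stop("node universes differ; missing in B: ",
         paste(missing_in_b, collapse = ", "), "; missing in A: ",
         paste(missing_in_a, collapse = ", "))
  }
  # map B's node ids onto A's ordering
  mapB <- match(keyB, keyA)
  mem <- partition$reported
  ncom <- max(mem, na.rm = TRUE)
  strength <- function(edges, map = NULL) {
    S <- matrix(0, ncom, ncom)
    if (nrow(edges) == 0L) return(S)
    i <- edges$i; j <- edges$j
    if (!is.null(map)) { i <- map[i]; j <- map[j] }
    ci <- mem[i]; cj <- mem[j]
    ok <- !is.na(ci) & !is.na(cj)
    for (e in which(ok)) {
      S[ci[e], cj[e]] <- S[ci[e], cj[e]] + edges$persistence[e]
      if (ci[e] != cj[e])
        S[cj[e], ci[e]] <- S[cj[e], ci[e]] + edges$persistence[e]
    }
    S
  }
  SA <- strength(graphA$edges)
  SB <- strength(graphB$edges, mapB)
  structure(list(change = SB - SA, strengthA = SA, strengthB = SB,
                 communities = seq_len(ncom)),
            class = "difference_network")
}

#' @export
print.difference_network <- function(x, ...) {
  cat("difference_network over", nrow(x$change), "communities; largest |change|",
      sprintf("%.3f\n", max(abs(x$change))))
  invisible(x)
}

#' Write a contact graph as an edge list (and optionally GraphML)
#' @param graph A `contact_graph`.
#' @param path Output path for the delimited edge list.
#' @param graphml Optional path for a GraphML copy (via igraph).
#' @return `path`, invisibly.
#' @export
write_contact_graph <- function(graph, path, graphml = NULL) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(graph), graphml, format = "graphml")
  invisible(path)
}
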