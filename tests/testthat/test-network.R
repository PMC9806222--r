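# Builds a CA-per-residue trajectory where residue pair contacts follow a
# scripted schedule: `schedule[[k]]` gives the frames in which pair k is in
# contact. Non-contacting residues sit far apart on a line.
scripted_contact_traj <- function(n_res, n_frames, schedule) {
  base <- cbind(seq_len(n_res) * 20, 0, 0)     # 20 A apart: never in contact
  xyz <- matrix(0, n_frames, 3 * n_res)
  for (f in seq_len(n_frames)) {
    X <- base
    for (k in seq_along(schedule)) {
      pr <- schedule[[k]]$pair
      if (f %in% schedule[[k]]$frames)
        X[pr[2], ] <- X[pr[1], ] + c(3, 0, 0)  # within 4.5 A
    }
    xyz[f, ] <- as.numeric(t(X))
  }
  toy_trajectory(xyz)
}

test_that("the persistence rule is strict: >75% makes an edge, 50% does not", {
  # pair (1,3) in contact 50% of frames; pair (2,4) in 76%; pair (1,5) in 100%
  tr <- scripted_contact_traj(6, 100, list(
    list(pair = c(1, 3), frames = 1:50),
    list(pair = c(2, 4), frames = 1:76),
    list(pair = c(1, 5), frames = 1:100)))
  g <- contact_persistence(tr, cutoff = 4.5, threshold = 0.75)
  key <- paste(g$edges$i, g$edges$j)
  expect_false("1 3" %in% key)
  expect_true("2 4" %in% key)
  expect_true("1 5" %in% key)
  expect_equal(g$edges$persistence[key == "2 4"], 0.76)
  expect_equal(g$edges$persistence[key == "1 5"], 1.0)
  # exactly at the threshold: 75% is not strictly greater
  tr75 <- scripted_contact_traj(4, 100, list(
    list(pair = c(1, 3), frames = 1:75)))
  g75 <- contact_persistence(tr75, 4.5, 0.75)
  expect_equal(nrow(g75$edges), 0L)
})

test_that("scripted schedules reproduce the hand-enumerated edge set", {
  # disjoint residue pairs so each contact is independent of the others
  sched <- list(
    list(pair = c(1, 3), frames = 1:9),     # 90%
    list(pair = c(2, 4), frames = 1:8),     # 80%
    list(pair = c(5, 7), frames = 1:7),     # 70% -> below threshold
    list(pair = c(6, 8), frames = 1:10))    # 100%
  tr <- scripted_contact_traj(8, 10, sched)
  g <- contact_persistence(tr, 4.5, 0.75)
  expect_equal(paste(g$edges$i, g$edges$j), c("1 3", "2 4", "6 8"))
  # brute-force per-frame check of the persistence values
  expect_equal(g$edges$persistence, c(0.9, 0.8, 1.0))
})

test_that("sequence neighbors are excluded and edges shrink with stricter rules", {
  # residues 1 and 2 adjacent in space AND sequence: no edge
  tr <- scripted_contact_traj(4, 10, list(
    list(pair = c(1, 2), frames = 1:10),
    list(pair = c(1, 3), frames = 1:10)))
  g <- contact_persistence(tr, 4.5, 0.75)
  expect_false("1 2" %in% paste(g$edges$i, g$edges$j))
  expect_true("1 3" %in% paste(g$edges$i, g$edges$j))
  # monotonicity in threshold and cutoff
  sched <- list(list(pair = c(1, 3), frames = 1:6),
                list(pair = c(2, 4), frames = 1:9))
  tr2 <- scripted_contact_traj(4, 10, sched)
  e_lo <- nrow(contact_persistence(tr2, 4.5, 0.5)$edges)
  e_hi <- nrow(contact_persistence(tr2, 4.5, 0.85)$edges)
  expect_gte(e_lo, e_hi)
  e_small <- nrow(contact_persistence(tr2, 2.0, 0.5)$edges)
  expect_gte(e_lo, e_small)
})

test_that("edge distances follow -log|C| with closed-form anchors", {
  g <- toy_graph(data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                            persistence = c(0.9, 0.8, 1)))
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 1
  C[1, 3] <- C[3, 1] <- exp(-1)
  C[2, 3] <- C[3, 2] <- -0.5
  w <- weight_edges(g, C)
  expect_equal(w$edges$distance, c(0, 1, -log(0.5)), tolerance = 1e-12)
  # independent arithmetic on a second toy
  C2 <- diag(3); C2[1, 2] <- C2[2, 1] <- 0.9
  C2[1, 3] <- C2[3, 1] <- 0.5; C2[2, 3] <- C2[3, 2] <- 0.1
  w2 <- weight_edges(g, C2)
  expect_equal(w2$edges$distance, -log(c(0.9, 0.5, 0.1)), tolerance = 1e-12)
  # C = 0 edges dropped with a warning; |C| > 1 is an upstream breach
  C3 <- diag(3); C3[1, 2] <- C3[2, 1] <- 0
  C3[1, 3] <- C3[3, 1] <- 0.5; C3[2, 3] <- C3[3, 2] <- 0.5
  expect_warning(w3 <- weight_edges(g, C3), "dropped")
  expect_equal(nrow(w3$edges), 2L)
  C4 <- C2; C4[1, 2] <- C4[2, 1] <- 1.2
  expect_error(weight_edges(g, C4), "invalid")
})

test_that("community detection matches exhaustive maximum modularity", {
  graphs <- list(
    k6 = clique_edges(1:6),
    two_k5 = rbind(clique_edges(1:5), clique_edges(6:10),
                   data.frame(i = 1, j = 6, persistence = 1)),
    two_k4 = rbind(clique_edges(1:4), clique_edges(5:8),
                   data.frame(i = 4, j = 5, persistence = 1)),
    three_cliques = rbind(clique_edges(1:4), clique_edges(5:7),
                          clique_edges(8:10),
                          data.frame(i = c(4, 7), j = c(5, 8),
                                     persistence = 1)),
    two_triangles = rbind(clique_edges(1:3), clique_edges(4:6),
                          data.frame(i = 3, j = 4, persistence = 1)))
  for (nm in names(graphs)) {
    ed <- graphs[[nm]]
    n <- max(ed$i, ed$j)
    part <- girvan_newman(toy_graph(ed), min_size = 1L)
    oracle <- exhaustive_max_modularity(ed, n)
    expect_equal(part$modularity, oracle$modularity, tolerance = 1e-9,
                 label = paste("modularity of", nm))
    expect_equal(edge_modularity(ed, part$membership), part$modularity,
                 tolerance = 1e-9)
  }
  # K6 has no internal structure: a single community
  expect_equal(length(unique(girvan_newman(toy_graph(clique_edges(1:6)),
                                           min_size = 1L)$membership)), 1L)
  # two K5 cliques joined by an edge split in two
  p <- girvan_newman(toy_graph(graphs$two_k5), min_size = 3L)
  expect_equal(length(p$sizes), 2L)
  expect_equal(unname(sort(as.integer(p$sizes))), c(5L, 5L))
  expect_equal(p$membership[1:5], rep(p$membership[1], 5))
})

test_that("communities smaller than the minimum size are omitted", {
  # two K4 cliques plus a dangling 2-node appendage
  ed <- rbind(clique_edges(1:4), clique_edges(5:8),
              data.frame(i = c(4, 5, 9), j = c(5, 9, 10),
                         persistence = c(1, 0.9, 0.9)))
  p <- girvan_newman(toy_graph(ed), min_size = 3L)
  expect_true(any(is.na(p$reported)))
  expect_true(all(as.integer(p$sizes) >= 3L))
  # with min_size 1 the small community is kept
  p1 <- girvan_newman(toy_graph(ed), min_size = 1L)
  expect_false(any(is.na(p1$reported)))
})

test_that("difference networks are zero on identity and antisymmetric", {
  ed <- rbind(clique_edges(1:4), clique_edges(5:8),
              data.frame(i = c(1, 2), j = c(5, 6), persistence = c(0.9, 0.8)))
  gA <- toy_graph(ed)
  pA <- girvan_newman(gA, min_size = 3L)
  dn0 <- difference_network(gA, pA, gA)
  expect_equal(max(abs(dn0$change)), 0)
  # deleting one inter-community edge of known weight w: change = -w
  edB <- ed[-(nrow(ed)), ]                   # drop the (2,6) edge, w = 0.8
  gB <- toy_graph(edB, n_nodes = 8)
  dn <- difference_network(gA, pA, gB)
  c1 <- pA$reported[2]; c2 <- pA$reported[6]
  expect_equal(dn$change[c1, c2], -0.8)
  expect_equal(dn$change[c2, c1], -0.8)
  # antisymmetry under swapping the states
  pB <- girvan_newman(gB, min_size = 3L)
  dAB <- difference_network(gA, pA, gB)$change
  dBA <- difference_network(gB, pA, gA)$change
  expect_equal(dAB, -dBA)
  # node-universe mismatch is an explicit error
  gSmall <- toy_graph(clique_edges(1:4))
  expect_error(difference_network(gA, pA, gSmall), "missing")
})

test_that("a persistence drop across a block interface shows as negative change", {
  # two square blocks of four residues; the single interface contact (3,5)
  # is present in 90% of frames in state A and only 40% in state B
  two_block_traj <- function(n_contact, n_frames = 100L) {
    sq <- rbind(c(0, 0), c(4.2, 4.2), c(4.2, 0), c(0, 4.2))
    xyz <- matrix(0, n_frames, 24)
    for (f in seq_len(n_frames)) {
      dx <- if (f <= n_contact) 8.2 else 12   # r3-r5 gap: 4.0 or 7.8 A
      X <- rbind(cbind(sq, 0), cbind(sweep(sq, 2, c(dx, 0), "+"), 0))
      xyz[f, ] <- as.numeric(t(X))
    }
    toy_trajectory(xyz)
  }
  gA <- contact_persistence(two_block_traj(90), 4.5, 0.75)
  gB <- contact_persistence(two_block_traj(40), 4.5, 0.75)
  expect_true("3 5" %in% paste(gA$edges$i, gA$edges$j))
  expect_false("3 5" %in% paste(gB$edges$i, gB$edges$j))
  pA <- girvan_newman(gA, min_size = 2L)
  dn <- difference_network(gA, pA, gB)
  expect_lt(min(dn$change), -0.8)
  c3 <- pA$reported[3]; c5 <- pA$reported[5]
  expect_equal(dn$change[c3, c5], -0.9)
})
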