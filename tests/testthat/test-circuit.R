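test_that("hub classes follow inclusive degree thresholds on distinct partners", {
  ids <- paste0("v", 1:30)
  A <- matrix(0, 30, 30, dimnames = list(ids, ids))
  A[2:26, 1] <- 1          # v1: 25 distinct inputs
  A[1, 2:4] <- 1           # v1: 3 outputs
  A[2, 5:24] <- 1          # v2: 20 outputs
  A[5:24, 2] <- 1          # v2: 20 inputs
  h <- hub_classification(A, in_thresh = 20, out_thresh = 20)
  expect_equal(h$class[h$node == "v1"], "in")
  expect_equal(h$class[h$node == "v2"], "in-out")  # >= is inclusive
  expect_true(all(h$class[h$node %in% paste0("v", 5:24)] == "none"))
  # the threshold derives from mean + 1.5 SD of the degree sequence:
  # a two-point sequence with mean 4 and SD 32/3 lands exactly on 20
  d <- (32 / 3) / sqrt(2)
  expect_equal(degree_threshold_from_stats(c(4 - d, 4 + d)), 20)
})

test_that("sensory orders take the minimum over modalities and flag unreachable nodes", {
  ids <- c("sn_o", "sn_v", "a", "b", "c", "iso")
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  A["sn_o", "a"] <- 1      # a: olfactory 2nd order
  A["a", "b"] <- 1         # b: olfactory 3rd order
  A["sn_v", "b"] <- 1      # ... but visual 2nd order -> overall 2nd
  A["b", "c"] <- 1
  so <- sensory_orders(A, list(olfactory = "sn_o", visual = "sn_v"))
  ord <- stats::setNames(so$orders$order, so$orders$node)
  expect_equal(unname(ord["a"]), 2)
  expect_equal(unname(ord["b"]), 2)
  expect_equal(unname(so$hops["b", "olfactory"]), 2)
  expect_equal(unname(ord["c"]), 3)
  expect_true(is.na(ord["iso"]))
  # unknown-modality exclusion
  so2 <- sensory_orders(A, list(olfactory = "sn_o"), exclude = "c")
  expect_true(is.na(stats::setNames(so2$orders$order, so2$orders$node)["c"]))
})

test_that("local neurons are classified by strict output/input majorities", {
  ids <- c("sn", "p1", "p2", "l1", "t2", "deep", "d2", "out")
  A <- matrix(0, 8, 8, dimnames = list(ids, ids))
  A["sn", c("p1", "p2", "l1")] <- 5
  A["sn", "t2"] <- 1
  # l1 is 2nd order and sends 80% of output into its own layer -> type 1 LN
  A["l1", "p1"] <- 4; A["l1", "deep"] <- 1
  # p1 and p2 project across layers -> PNs by exclusion
  A["p1", "deep"] <- 5
  A["p2", "d2"] <- 5
  # t2 is 2nd order but takes 75% of input from and sends all output to the
  # 3rd-order stratum it does not belong to -> type 2 LN
  A["deep", "t2"] <- 3
  A["t2", "d2"] <- 2
  # deep spreads output across layers -> non-LN
  A["deep", "out"] <- 7
  so <- sensory_orders(A, list(somato = "sn"))
  ln <- local_neuron_classification(A, so, inputs = "sn", outputs = "out")
  cls <- stats::setNames(ln$class, ln$node)
  expect_equal(unname(cls["l1"]), "type1_LN")
  expect_equal(unname(cls["t2"]), "type2_LN")
  expect_equal(unname(cls["p1"]), "PN")
  expect_equal(unname(cls["p2"]), "PN")
  expect_equal(unname(cls["deep"]), "non-LN")
  expect_equal(unname(cls["d2"]), "non-LN")
})

test_that("pathway enumeration matches a DFS oracle and caps with exact totals", {
  # chain and complete bipartite sanity cases
  ids <- c("s", "a", "b", "t")
  A <- matrix(0, 4, 4, dimnames = list(ids, ids))
  A["s", "a"] <- 1; A["a", "t"] <- 1
  p1 <- enumerate_pathways(A, "s", "t", max_hops = 6)
  expect_equal(p1$total_count, 1)
  expect_equal(p1$paths[[1]], c("s", "a", "t"))
  A["s", "b"] <- 1; A["b", "t"] <- 1
  expect_equal(enumerate_pathways(A, "s", "t")$total_count, 2)
  expect_error(enumerate_pathways(A, "s", "s"), "disjoint")
  # random DAGs against the oracle
  for (seed in 1:8) {
    set.seed(seed)
    n <- 12
    B <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < 0.3) B[i, j] <- 1
    src <- c("n1", "n2"); tgt <- c("n11", "n12")
    got <- enumerate_pathways(B, src, tgt, max_hops = 5)
    want <- dfs_paths(B, src, tgt, 5)
    expect_equal(got$total_count, length(want))
    expect_setequal(vapply(got$paths, paste, "", collapse = ">"),
                    vapply(want, paste, "", collapse = ">"))
    capped <- enumerate_pathways(B, src, tgt, max_hops = 5,
                                 sample_cap = 3, seed = 1)
    expect_equal(capped$total_count, length(want))
    expect_lte(length(capped$paths), 3)
  }
})

test_that("laterality cutoffs map fractions to the three classes", {
  expect_equal(axon_laterality(c(0, 1, 0.5, NA, 0.2, 0.8)),
               c("ipsilateral", "contralateral", "bilateral", NA,
                 "ipsilateral", "contralateral"))
})

test_that("bilateral partner similarity compares homolog-indexed output vectors", {
  ids <- c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4")
  pm <- pair_map(paste0("L", 1:4), paste0("R", 1:4))
  hemi <- stats::setNames(rep(c("left", "right"), each = 4), ids)
  A <- matrix(0, 8, 8, dimnames = list(ids, ids))
  # identical partners both sides -> 1
  A["L1", c("L2", "L3")] <- 2; A["L1", c("R2", "R3")] <- 2
  expect_equal(bilateral_partner_similarity(A, pm, "L1", hemi), 1)
  # disjoint partner sets -> 0
  A2 <- matrix(0, 8, 8, dimnames = list(ids, ids))
  A2["L1", "L2"] <- 1; A2["L1", "R3"] <- 1
  expect_equal(bilateral_partner_similarity(A2, pm, "L1", hemi), 0)
  # hand cosine: (1,1,0) vs (1,0,1) -> 0.5
  A3 <- matrix(0, 8, 8, dimnames = list(ids, ids))
  A3["L1", c("L2", "L3")] <- 1; A3["L1", c("R2", "R4")] <- 1
  expect_equal(bilateral_partner_similarity(A3, pm, "L1", hemi), 0.5)
  # no contralateral output -> undefined
  A4 <- matrix(0, 8, 8, dimnames = list(ids, ids))
  A4["L1", "L2"] <- 1
  expect_true(is.na(bilateral_partner_similarity(A4, pm, "L1", hemi)))
})

test_that("homolog pair loops aggregate into double and super loops via inter-pair edges", {
  ids <- c(paste0("L", 1:4), paste0("R", 1:4))
  pm <- pair_map(paste0("L", 1:4), paste0("R", 1:4))
  A <- matrix(0, 8, 8, dimnames = list(ids, ids))
  none <- homolog_reciprocal_loops(A, pm)
  expect_equal(nrow(none$pair_loops), 0)
  A["L1", "R1"] <- 1; A["R1", "L1"] <- 1
  one <- homolog_reciprocal_loops(A, pm)
  expect_equal(nrow(one$pair_loops), 1)
  expect_equal(one$double_loops, 0)
  # second pair loop linked by an inter-pair edge -> double loop
  A["L2", "R2"] <- 1; A["R2", "L2"] <- 1
  A["L1", "R2"] <- 1
  two <- homolog_reciprocal_loops(A, pm)
  expect_equal(two$double_loops, 1)
  # third linked loop -> super loop
  A["L3", "R3"] <- 1; A["R3", "L3"] <- 1
  A["R2", "L3"] <- 1
  three <- homolog_reciprocal_loops(A, pm)
  expect_equal(three$double_loops, 0)
  expect_equal(three$super_loops, 1)
})

test_that("group connection probabilities match hand counts", {
  ids <- paste0("v", 1:7)
  A <- matrix(0, 7, 7, dimnames = list(ids, ids))
  groups <- stats::setNames(c("a", "a", "b", "b", "b", "c", "c"), ids)
  # complete bipartite a -> b
  A[1:2, 3:5] <- 1
  M <- group_connection_probability(A, groups)
  expect_equal(unname(M["a", "b"]), 1)
  expect_equal(unname(M["b", "a"]), 0)
  # hand-built entries
  A[3, 4] <- 1; A[6, 7] <- 1; A[7, 6] <- 1
  M2 <- group_connection_probability(A, groups)
  expect_equal(unname(M2["b", "b"]), 1 / 6)
  expect_equal(unname(M2["c", "c"]), 1)
  expect_equal(unname(M2["a", "a"]), 0)
  empty <- group_connection_probability(matrix(0, 7, 7, dimnames = list(ids, ids)),
                                        groups)
  expect_true(all(empty == 0))
})

test_that("zigzag motifs require distinct flanking DNs; reciprocal DN-AN loops are separate", {
  ids <- c("D1", "D2", "A1", "x")
  A <- matrix(0, 4, 4, dimnames = list(ids, ids))
  A["D1", "A1"] <- 1; A["A1", "D2"] <- 1
  z <- zigzag_motifs(A, dn_set = c("D1", "D2"), an_set = "A1")
  expect_equal(nrow(z$zigzags), 1)
  expect_equal(z$zigzags$dn1, "D1")
  expect_equal(nrow(z$reciprocal_loops), 0)
  # D1 -> A1 -> D1 only: a reciprocal loop, not a zigzag
  B <- matrix(0, 4, 4, dimnames = list(ids, ids))
  B["D1", "A1"] <- 1; B["A1", "D1"] <- 1
  z2 <- zigzag_motifs(B, dn_set = c("D1", "D2"), an_set = "A1")
  expect_equal(nrow(z2$zigzags), 0)
  expect_equal(nrow(z2$reciprocal_loops), 1)
  # extended leg through an intermediate gives a 4-node motif
  C <- matrix(0, 4, 4, dimnames = list(ids, ids))
  C["D1", "x"] <- 1; C["x", "A1"] <- 1; C["A1", "D2"] <- 1
  z3 <- zigzag_motifs(C, dn_set = c("D1", "D2"), an_set = "A1", max_leg = 2)
  expect_equal(nrow(z3$zigzags), 1)
  expect_equal(z3$zigzags$n_nodes, 4)
  expect_equal(nrow(zigzag_motifs(C, c("D1", "D2"), "A1", max_leg = 1)$zigzags), 0)
})

test_that("direct zigzag counts equal brute-force triple enumeration on random graphs", {
  for (seed in 1:6) {
    A <- random_digraph(12, 0.25, seed = seed)
    dn <- paste0("n", 1:4); an <- paste0("n", 5:7)
    z <- zigzag_motifs(A, dn, an, max_leg = 1)
    brute <- 0
    for (d1 in dn) for (a in an) for (d2 in dn)
      if (d1 != d2 && A[d1, a] > 0 && A[a, d2] > 0) brute <- brute + 1
    expect_equal(nrow(z$zigzags), brute)
  }
})
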