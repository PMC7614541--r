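chain_graph <- function(ids, w = 1) {
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(length(ids) - 1)) A[ids[k], ids[k + 1]] <- w
  A
}

test_that("activation probabilities match closed forms on chains and fans", {
  p <- 0.05; iters <- 10000
  A <- chain_graph(c("A", "B", "C"))
  r <- run_cascade(A, cascade_spec("A", p = p, max_hops = 3,
                                   iterations = iters, seed = 4))
  sd3 <- function(q) 3 * sqrt(q * (1 - q) / iters)
  expect_lt(abs(r$activation_probability["B", "hop1"] - p), sd3(p))
  expect_lt(abs(r$activation_probability["C", "hop2"] - p^2), sd3(p^2))
  # fan-in: two start nodes with unit weights onto B -> complement rule
  F <- matrix(0, 3, 3, dimnames = rep(list(c("s1", "s2", "B")), 2))
  F["s1", "B"] <- 1; F["s2", "B"] <- 1
  rf <- run_cascade(F, cascade_spec(c("s1", "s2"), p = p, max_hops = 1,
                                    iterations = iters, seed = 5))
  q <- 1 - 0.95^2
  expect_lt(abs(rf$activation_probability["B", "hop1"] - q), sd3(q))
  # weighted edge: weight w behaves as w independent synapses
  W <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  W["A", "B"] <- 10
  rw <- run_cascade(W, cascade_spec("A", p = p, max_hops = 1,
                                    iterations = iters, seed = 6))
  qw <- 1 - 0.95^10
  expect_lt(abs(rw$activation_probability["B", "hop1"] - qw), sd3(qw))
})

test_that("stop nodes become active but never propagate", {
  A <- chain_graph(c("A", "B", "C"), w = 60)  # near-certain transmission
  r <- run_cascade(A, cascade_spec("A", stop = "B", p = 0.05, max_hops = 4,
                                   iterations = 500, seed = 7))
  expect_gt(r$visit_probability["B"], 0.9)
  expect_equal(unname(r$visit_probability["C"]), 0)
})

test_that("cascades are bit-reproducible and respect single activation per run", {
  g <- generate_connectome(generator_config(n_pairs = 25, seed = 2))
  spec <- cascade_spec(g$truth$pair_map$left[1:3], p = 0.1, max_hops = 6,
                       iterations = 300, seed = 11)
  r1 <- run_cascade(g$connectome, spec)
  r2 <- run_cascade(g$connectome, spec)
  expect_identical(r1$activation_probability, r2$activation_probability)
  # each node activates at most once per iteration, so hop-probabilities of a
  # node sum to at most 1 and never exceed its visit probability total
  expect_true(all(rowSums(r1$activation_probability) <= 1 + 1e-12))
  expect_true(all(abs(rowSums(r1$activation_probability) -
                        r1$visit_probability) < 1e-12))
})

test_that("adding an edge never decreases visit probabilities beyond MC noise", {
  A <- random_digraph(15, 0.15, seed = 20, weights = 1:3)
  spec <- cascade_spec("n1", p = 0.3, max_hops = 5, iterations = 3000, seed = 3)
  base <- run_cascade(A, spec)$visit_probability
  A2 <- A
  A2["n1", "n8"] <- A2["n1", "n8"] + 5
  more <- run_cascade(A2, spec)$visit_probability
  expect_true(all(more - base > -0.05))
  expect_gt(more["n8"], base["n8"])
})

test_that("receives_signal is a strict majority rule", {
  r <- list(visit_probability = c(a = 0.9, b = 0.5, c = 0.51))
  class(r) <- "cascade_result"
  expect_equal(unname(receives_signal(r)), c(TRUE, FALSE, TRUE))
})

test_that("deterministic-limit cascades reach the whole chain", {
  A <- chain_graph(paste0("v", 1:6), w = 200)
  r <- run_cascade(A, cascade_spec("v1", p = 0.05, max_hops = 6,
                                   iterations = 200, seed = 8))
  expect_true(all(receives_signal(r)))
})

test_that("modality integration labels labeled lines and convergence nodes", {
  # two labeled-line chains converging on one node
  ids <- c("s1", "a1", "s2", "a2", "conv")
  A <- matrix(0, 5, 5, dimnames = list(ids, ids))
  A["s1", "a1"] <- 60; A["s2", "a2"] <- 60
  A["a1", "conv"] <- 60; A["a2", "conv"] <- 60
  mk <- function(start, seed) run_cascade(A, cascade_spec(start, p = 0.05,
                                                          max_hops = 4,
                                                          iterations = 400,
                                                          seed = seed))
  mi <- modality_integration(list(m1 = mk("s1", 1), m2 = mk("s2", 2)))
  expect_equal(mi$label[mi$node == "a1"], "unimodal")
  expect_equal(mi$label[mi$node == "a2"], "unimodal")
  expect_equal(mi$label[mi$node == "conv"], "multimodal")
  expect_equal(mi$combination[mi$node == "conv"], "m1+m2")
})

test_that("lateralization is balanced on a perfectly mirrored connectome", {
  cfg <- generator_config(n_pairs = 30, mirror_noise = 0, seed = 13)
  g <- generate_connectome(cfg)
  pm <- g$truth$pair_map
  inputs <- g$connectome$meta$node_id[g$connectome$meta$is_input]
  li <- intersect(inputs, pm$left); ri <- pm$right[match(li, pm$left)]
  A <- as.matrix(layer_adjacency(g$connectome, "ad"))
  lr <- run_cascade(A, cascade_spec(li, p = 0.2, max_hops = 4,
                                    iterations = 3000, seed = 5))
  rr <- run_cascade(A, cascade_spec(ri, p = 0.2, max_hops = 4,
                                    iterations = 3000, seed = 6))
  lat <- lateralization(lr, rr)
  ok <- lat$flag == "integrative"
  expect_true(any(ok))
  expect_lt(max(abs(lat$ratio[ok] - 0.5)), 0.2)
  # degenerate flags
  none <- lateralization(
    structure(list(visit_probability = c(x = 0)), class = "cascade_result"),
    structure(list(visit_probability = c(x = 0)), class = "cascade_result"))
  expect_equal(none$flag, "no_signal")
})

test_that("recurrence is zero on feedforward chains and one on strong 2-cycles", {
  A <- chain_graph(paste0("v", 1:5), w = 60)
  rc <- recurrence_fraction(A, hops = 5, p = 0.05, iterations = 300, seed = 2)
  expect_true(all(rc$recurrence[!is.na(rc$recurrence)] == 0))
  B <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  B["A", "B"] <- 60; B["B", "A"] <- 60
  rb <- recurrence_fraction(B, neurons = "A", hops = 5, p = 0.05,
                            iterations = 300, seed = 3)
  expect_equal(rb$recurrence, 1)
  expect_gte(rb$mean_return_lengths, 1)
})

test_that("planted recurrent loops score higher than matched non-loop nodes", {
  cfg <- generator_config(n_pairs = 40, n_blocks = 4, mirror_noise = 0,
                          n_recurrent_loops = 2, feedforward_bias = 0.9,
                          seed = 31)
  g <- generate_connectome(cfg)
  A <- as.matrix(layer_adjacency(g$connectome, "ad"))
  loop_nodes <- unlist(lapply(g$truth$recurrent_loops, `[[`, "left"))
  others <- setdiff(g$truth$pair_map$left, loop_nodes)
  rc <- recurrence_fraction(A, neurons = c(loop_nodes, others), hops = 5,
                            p = 0.05, iterations = 200, seed = 4)
  lo <- rc$recurrence[match(loop_nodes, rc$neuron)]
  ot <- rc$recurrence[match(others, rc$neuron)]
  expect_gt(min(lo, na.rm = TRUE), mean(ot, na.rm = TRUE))
})

test_that("cluster flow matrix is upper-triangular for feedforward cluster chains", {
  ids <- paste0("v", 1:9)
  A <- matrix(0, 9, 9, dimnames = list(ids, ids))
  cl <- stats::setNames(rep(c("c1", "c2", "c3"), each = 3), ids)
  for (k in 1:3) for (j in 1:3)
    A[ids[k], ids[3 + j]] <- 40
  for (k in 1:3) for (j in 1:3)
    A[ids[3 + k], ids[6 + j]] <- 40
  z <- signal_flow(A)
  M <- cluster_flow_matrix(A, cl, z, hops = 2, p = 0.05, iterations = 300,
                           seed = 9)
  expect_equal(M$order, c("c1", "c2", "c3"))
  expect_equal(M$backward, 0)
  expect_gt(M$forward, 0)
  # one planted back-edge produces a below-diagonal entry
  A2 <- A; A2[ids[7], ids[1]] <- 40
  z2 <- signal_flow(A2)
  M2 <- cluster_flow_matrix(A2, cl, z2, hops = 2, p = 0.05, iterations = 300,
                            seed = 9)
  expect_gt(M2$backward, 0)
})

test_that("efference-copy partners split into recurrent and parallel like brute force", {
  for (seed in 1:6) {
    A <- random_digraph(12, 0.2, seed = seed)
    outs <- c("n1", "n2")
    res <- efference_copy_reach(A, outs, hops = 2)
    partners <- attr(res, "partners")
    B <- (A > 0) * 1
    for (o in outs) {
      down <- brute_reach(B, o, 2, "out")
      up <- brute_reach(B, o, 2, "in")
      got <- partners[partners$output == o, ]
      expect_setequal(got$partner, down)
      expect_setequal(got$partner[got$class == "recurrent"], intersect(down, up))
    }
  }
})
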