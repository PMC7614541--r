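test_that("hemisphere subgraph splitting places edges in the right quadrants", {
  ids <- c("L1", "L2", "R1", "R2")
  tab <- synapse_table(c("L1", "L1"), c("L2", "R1"), "axon", "dendrite", c(3, 2))
  meta <- node_meta(ids, hemisphere = c("left", "left", "right", "right"))
  cx <- build_multiplex(tab, meta)
  pm <- pair_map(c("L1", "L2"), c("R1", "R2"))
  sg <- split_hemisphere_subgraphs(cx, pm, type = "ad")
  expect_equal(unname(sg$LL["L1", "L2"]), 3)
  expect_equal(unname(sg$LR["L1", "R1"]), 2)
  expect_equal(sum(sg$RL), 0)
  expect_equal(sum(sg$RR), 0)
  # mirror-symmetric connectome: LL equals RR under the pair permutation
  g <- generate_connectome(generator_config(n_pairs = 30, mirror_noise = 0, seed = 8))
  sg2 <- split_hemisphere_subgraphs(g$connectome, g$truth$pair_map)
  expect_equal(unname(sg2$LL), unname(sg2$RR))
  expect_equal(unname(sg2$LR), unname(sg2$RL))
})

test_that("pass-to-ranks replaces weights by scaled average ranks and preserves order", {
  A <- matrix(c(0, 1, 1, 3), 2, 2)
  P <- pass_to_ranks(A)
  expect_equal(sort(P[P > 0]), c(0.5, 0.5, 1))
  expect_equal(P[A == 0], 0)
  eq <- pass_to_ranks(matrix(c(0, 2, 2, 2), 2, 2))
  expect_true(all(eq[eq > 0] == eq[2]))
  R <- random_digraph(15, 0.3, seed = 4, weights = 1:10)
  PR <- pass_to_ranks(R)
  nz <- which(R > 0)
  ord <- order(R[nz])
  expect_true(all(diff(PR[nz][ord]) >= 0))
  expect_error(pass_to_ranks(matrix(-1, 1, 1)), "nonnegative")
})

test_that("spectral embedding is exchangeable on rank-1 blocks and near-optimal in rank", {
  A <- matrix(1, 6, 6)  # rank-1 block of exchangeable nodes
  expect_warning(e <- adjacency_spectral_embedding(A, 2, augment = FALSE),
                 "rank")
  expect_lt(max(stats::dist(e$out)), 1e-8)  # identical nodes embed identically
  # Eckart-Young: rank-d reconstruction error bounded by the (d+1)-th singular value
  R <- random_digraph(15, 0.4, seed = 2, weights = 1:4)
  sv <- svd(R)$d
  e2 <- adjacency_spectral_embedding(R, 5, augment = FALSE)
  err <- norm(R - e2$out %*% t(e2$in_), "2")
  expect_lte(err, sv[6] + 1e-8)
  expect_warning(adjacency_spectral_embedding(matrix(1, 3, 3), 10), "reduced")
})

test_that("embedding a 2-block SBM separates the blocks", {
  set.seed(42)
  n <- 120
  block <- rep(1:2, each = n / 2)
  P <- ifelse(outer(block, block, "=="), 0.3, 0.05)
  A <- matrix(stats::rbinom(n * n, 1, P), n, n); diag(A) <- 0
  e <- adjacency_spectral_embedding(A, 2)
  km <- stats::kmeans(e$out, 2, nstart = 10)
  expect_gt(mclust::adjustedRandIndex(km$cluster, block), 0.9)
})

test_that("Procrustes alignment inverts a planted rotation and degrades smoothly with noise", {
  set.seed(7)
  X <- matrix(stats::rnorm(60 * 4), 60, 4)
  Q0 <- qr.Q(qr(matrix(stats::rnorm(16), 4, 4)))
  al <- align_embeddings(X, X %*% Q0)
  expect_lt(al$residual, 1e-8)
  expect_lt(max(abs(al$Y_aligned - X)), 1e-8)
  id <- align_embeddings(X, X)
  expect_lt(max(abs(id$Q - diag(4))), 1e-8)
  res <- sapply(c(0.01, 0.1, 0.5, 1), function(s)
    align_embeddings(X, X %*% Q0 + matrix(stats::rnorm(240, sd = s), 60, 4))$residual)
  expect_true(all(diff(res) > 0))
})

test_that("joint embedding collapses homologs at zero noise and is permutation equivariant", {
  cfg <- generator_config(n_pairs = 60, mirror_noise = 0, seed = 15)
  g <- generate_connectome(cfg)
  emb <- joint_embedding(g$connectome, g$truth$pair_map, d1 = 8, d2 = 4)
  expect_lt(max(abs(emb$left - emb$right)), 1e-6)
  # silhouette-style check: planted blocks separate in the pair embedding
  cfg2 <- generator_config(n_pairs = 160, n_blocks = 4, mirror_noise = 0.05,
                           feedforward_bias = 0.5, seed = 16)
  g2 <- generate_connectome(cfg2)
  emb2 <- joint_embedding(g2$connectome, g2$truth$pair_map, d1 = 12, d2 = 6)
  tb <- g2$truth$block_of[rownames(emb2$pair_positions)]
  km <- stats::kmeans(emb2$pair_positions, 4, nstart = 20)
  expect_gt(mclust::adjustedRandIndex(km$cluster, tb), 0.8)
})

test_that("recursive GMM splits well-separated blobs once and respects the size cutoff", {
  set.seed(3)
  X <- rbind(matrix(stats::rnorm(100 * 3), 100, 3),
             matrix(stats::rnorm(100 * 3, mean = 10), 100, 3))
  rownames(X) <- paste0("p", 1:200)
  tree <- recursive_gmm_cluster(X, max_depth = 4, min_size = 150)
  expect_equal(sort(unique(tree$labels)), c("1", "2"))
  expect_equal(unname(table(tree$labels, rep(1:2, each = 100)))[1, 2], 0)
  # a 31-member group is never split
  X31 <- rbind(matrix(stats::rnorm(16 * 2), 16, 2),
               matrix(stats::rnorm(15 * 2, mean = 10), 15, 2))
  rownames(X31) <- paste0("q", 1:31)
  t31 <- recursive_gmm_cluster(X31, max_depth = 4, min_size = 32)
  expect_equal(unique(t31$labels), "root")
  # a single isotropic blob stays whole
  set.seed(4)
  X1 <- matrix(stats::rnorm(500 * 3), 500, 3)
  rownames(X1) <- paste0("r", 1:500)
  t1 <- recursive_gmm_cluster(X1, max_depth = 2, min_size = 32)
  expect_equal(unique(t1$labels), "root")
})

test_that("cluster trees refine strictly across levels and label both homologs", {
  cfg <- generator_config(n_pairs = 150, n_blocks = 4, mirror_noise = 0.05,
                          feedforward_bias = 0.5, seed = 19)
  g <- generate_connectome(cfg)
  emb <- joint_embedding(g$connectome, g$truth$pair_map, d1 = 16, d2 = 8)
  tree <- recursive_gmm_cluster(emb, max_depth = 6, min_size = 32)
  depths <- seq_len(max(lengths(strsplit(tree$labels, ".", fixed = TRUE))))
  for (d in depths[-1]) {
    coarse <- cut_tree(tree, d - 1)
    fine <- cut_tree(tree, d)
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
  lab <- cluster_labels(tree, g$truth$pair_map)
  pm <- g$truth$pair_map
  expect_equal(unname(lab[pm$left]), unname(lab[pm$right]))
})

test_that("morphology scores sit at chance for random clusters and at the ceiling for tight ones", {
  set.seed(11)
  n <- 40
  ids <- paste0("c", 1:n)
  # random similarities, random clusters: mean score ~ 0.5
  means <- replicate(60, {
    S <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    cl <- stats::setNames(sample(1:4, n, replace = TRUE), ids)
    mean(cluster_morphology_score(S, cl), na.rm = TRUE)
  })
  expect_lt(abs(mean(means) - 0.5), 0.03)
  # a cluster whose members are mutually top-ranked scores near 1
  S <- matrix(stats::runif(n * n, 0, 0.5), n, n, dimnames = list(ids, ids))
  S[1:5, 1:5] <- stats::runif(25, 0.9, 1)
  cl <- stats::setNames(c(rep("tight", 5), rep("rest", n - 5)), ids)
  sc <- cluster_morphology_score(S, cl)
  expect_gt(sc["tight"], 0.95)
  expect_error(cluster_morphology_score(matrix(-1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
                                        stats::setNames(c("x", "x"), c("a", "b"))),
               "nonnegative")
  # identical rows give equal within-cluster scores
  E <- matrix(0.4, 10, 10, dimnames = list(paste0("e", 1:10), paste0("e", 1:10)))
  cle <- stats::setNames(rep(c("u", "v"), each = 5), paste0("e", 1:10))
  sce <- cluster_morphology_score(E, cle)
  expect_equal(unname(sce["u"]), unname(sce["v"]))
  # bilateral averaging
  bil <- bilateral_morphology_score(E, E, cle)
  expect_equal(unname(bil["u"]), unname(sce["u"]))
})
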