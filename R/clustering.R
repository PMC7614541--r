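#' Split a connectome into the four hemisphere subgraphs
#'
#' Returns the left-to-left (LL), right-to-right (RR), left-to-right (LR)
#' and right-to-left (RL) adjacencies, indexed so that homologous pairs
#' occupy corresponding rows/columns (row i of LL and row i of RR are the
#' two members of pair i). Unpaired nodes are excluded and reported.
#'
#' @param connectome a `multiplex_connectome`.
#' @param pairs a [pair_map()].
#' @param type layer selector (default `"sum"`: all connection types).
#' @return list with `LL`, `RR`, `LR`, `RL` (dense matrices), `left`,
#'   `right` (node id order) and `excluded` (unpaired / uncovered ids).
#' @export
split_hemisphere_subgraphs <- function(connectome, pairs, type = "sum") {
  A <- as_adjacency(connectome, type)
  ids <- rownames(A)
  if (inherits(connectome, "multiplex_connectome")) {
    hemi <- connectome$meta$hemisphere
    nohemi <- ids[!hemi %in% c("left", "right")]
    paired <- c(pairs$left, pairs$right)
    bad <- setdiff(paired, ids)
    if (length(bad) > 0)
      stop("pair map references nodes absent from connectome: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  keep <- pairs$left %in% ids & pairs$right %in% ids
  l <- pairs$left[keep]; r <- pairs$right[keep]
  li <- match(l, ids); ri <- match(r, ids)
  list(LL = A[li, li, drop = FALSE], RR = A[ri, ri, drop = FALSE],
       LR = A[li, ri, drop = FALSE], RL = A[ri, li, drop = FALSE],
       left = l, right = r,
       excluded = setdiff(ids, c(l, r)))
}

#' Pass-to-ranks edge-weight regularization
#'
#' Replaces every nonzero edge weight with its average-tie rank among the
#' nonzero weights, scaled into `(0, 1]` (rank divided by the number of
#' nonzero entries). Zero entries stay zero; the transform is
#' order-preserving and tames skewed weight distributions before spectral
#' embedding.
#'
#' @param A a nonnegative weight matrix.
#' @return matrix of the same shape.
#' @export
pass_to_ranks <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("weights must be nonnegative")
  nz <- which(A > 0)
  if (length(nz) == 0) return(A)
  A[nz] <- rank(A[nz], ties.method = "average") / length(nz)
  A
}

#' Adjacency spectral embedding
#'
#' Rank-`d` truncated singular value decomposition of the (diagonally
#' augmented) adjacency: out-latent positions from the left singular
#' vectors and in-latent positions from the right, each scaled by the
#' square root of the singular values.
#'
#' @param A adjacency matrix (square or rectangular).
#' @param d embedding dimension; reduced with a warning when it exceeds the
#'   numerical rank.
#' @param augment add `row degree / n` to the diagonal of square matrices
#'   to stabilize sparse embeddings (default TRUE).
#' @return list of class `ase`: `out` and `in_` position matrices, `d`,
#'   `singular_values`.
#' @export
adjacency_spectral_embedding <- function(A, d, augment = TRUE) {
  A <- as.matrix(A)
  if (augment && nrow(A) == ncol(A))
    diag(A) <- diag(A) + rowSums(A) / nrow(A)
  d_max <- min(dim(A))
  if (d > d_max) { warning("d exceeds matrix dimension; reduced"); d <- d_max }
  s <- svd(A, nu = d, nv = d)
  rk <- sum(s$d > max(dim(A)) * .Machine$double.eps * max(s$d, 1))
  if (d > rk && rk > 0) {
    warning("d exceeds numerical rank (", rk, "); reduced")
    d <- rk
  }
  scale <- sqrt(s$d[seq_len(d)])
  out <- s$u[, seq_len(d), drop = FALSE] %*% diag(scale, d)
  in_ <- s$v[, seq_len(d), drop = FALSE] %*% diag(scale, d)
  rownames(out) <- rownames(A); rownames(in_) <- colnames(A)
  structure(list(out = out, in_ = in_, d = d,
                 singular_values = s$d[seq_len(d)]), class = "ase")
}

#' Orthogonal Procrustes alignment of two embeddings
#'
#' Finds the orthogonal transform `Q` minimizing `||X_s - Y_s Q||_F` over
#' the seed-corresponded rows and returns `Y Q`. Used to remove the
#' orthogonal nonidentifiability of spectral embeddings before comparing
#' hemispheres.
#'
#' @param X,Y position matrices with matching column dimension.
#' @param seeds 2-column index matrix of corresponding rows (X row, Y row);
#'   `NULL` uses full row correspondence.
#' @return list: `Y_aligned`, `Q`, `residual` (Frobenius norm over seeds).
#' @export
align_embeddings <- function(X, Y, seeds = NULL) {
  stopifnot(ncol(X) == ncol(Y))
  if (is.null(seeds)) {
    stopifnot(nrow(X) == nrow(Y))
    seeds <- cbind(seq_len(nrow(X)), seq_len(nrow(Y)))
  }
  if (nrow(seeds) < ncol(X))
    warning("fewer seed rows than dimensions; alignment may be unstable")
  Xs <- X[seeds[, 1], , drop = FALSE]; Ys <- Y[seeds[, 2], , drop = FALSE]
  M <- crossprod(Ys, Xs)
  if (all(M == 0)) {
    Q <- diag(ncol(X))
  } else {
    s <- svd(M)
    Q <- s$u %*% t(s$v)
  }
  Ya <- Y %*% Q
  list(Y_aligned = Ya, Q = Q,
       residual = sqrt(sum((Xs - Ys %*% Q)^2)))
}

#' Joint left-right spectral embedding of homolog pairs
#'
#' Embeds the LL, RR, LR and RL subgraphs (after pass-to-ranks) with the
#' adjacency spectral embedding at dimension `d1`, aligns the right
#' hemisphere's positions onto the left's by orthogonal Procrustes over the
#' homolog-pair correspondence, concatenates each node's ipsilateral and
#' contralateral in/out positions, projects the stacked representation to
#' dimension `d2` with a second singular value decomposition, and averages
#' the left and right rows of each homolog pair. The result is one latent
#' position per pair, so downstream clustering assigns homologs
#' identically by construction.
#'
#' @param connectome a `multiplex_connectome`.
#' @param pairs a [pair_map()].
#' @param d1 per-subgraph embedding dimension (default 24).
#' @param d2 final joint dimension (default 10).
#' @param type layer selector (default `"sum"`).
#' @return list of class `joint_embedding`: `pair_positions` (one row per
#'   pair, rownames = left ids), `left`, `right` (pre-averaging positions),
#'   `d1`, `d2`, `alignment_residuals`, `subgraphs`.
#' @export
joint_embedding <- function(connectome, pairs, d1 = 24, d2 = 10, type = "sum") {
  sg <- split_hemisphere_subgraphs(connectome, pairs, type = type)
  m <- length(sg$left)
  d1 <- min(d1, m)
  emb <- lapply(sg[c("LL", "RR", "LR", "RL")], function(A)
    suppressWarnings(adjacency_spectral_embedding(pass_to_ranks(A), d1)))
  dd <- min(vapply(emb, function(e) e$d, numeric(1)))
  trim <- function(M) M[, seq_len(dd), drop = FALSE]
  a_oo <- align_embeddings(trim(emb$LL$out), trim(emb$RR$out))
  a_ii <- align_embeddings(trim(emb$LL$in_), trim(emb$RR$in_))
  a_co <- align_embeddings(trim(emb$LR$out), trim(emb$RL$out))
  a_ci <- align_embeddings(trim(emb$RL$in_), trim(emb$LR$in_))
  Zl <- cbind(trim(emb$LL$out), trim(emb$LL$in_), trim(emb$LR$out), trim(emb$RL$in_))
  Zr <- cbind(a_oo$Y_aligned, a_ii$Y_aligned, a_co$Y_aligned, a_ci$Y_aligned)
  Z <- rbind(Zl, Zr)
  d2 <- min(d2, ncol(Z), nrow(Z))
  s <- svd(Z, nu = d2, nv = d2)
  scores <- s$u %*% diag(s$d[seq_len(d2)], d2)
  left <- scores[seq_len(m), , drop = FALSE]
  right <- scores[m + seq_len(m), , drop = FALSE]
  pairpos <- (left + right) / 2
  rownames(pairpos) <- rownames(left) <- rownames(right) <- sg$left
  structure(list(pair_positions = pairpos, left = left, right = right,
                 d1 = dd, d2 = d2,
                 alignment_residuals = c(ipsi_out = a_oo$residual,
                                         ipsi_in = a_ii$residual,
                                         contra_out = a_co$residual,
                                         contra_in = a_ci$residual),
                 subgraphs = sg[c("left", "right", "excluded")]),
            class = "joint_embedding")
}

# fit 1- and 2-component Gaussian mixtures and report BICs (higher better);
# the covariance structure is itself selected by BIC within each G, which
# guards against overfitting an unconstrained covariance on small groups
fit_gmm_pair <- function(X) {
  fit <- function(G, prior = NULL) {
    tryCatch(mclust::Mclust(X, G = G, prior = prior, verbose = FALSE),
             error = function(e) NULL)
  }
  f1 <- fit(1); f2 <- fit(2)
  if (is.null(f1) || is.null(f1$bic) || is.na(f1$bic) ||
      is.null(f2) || is.null(f2$bic) || is.na(f2$bic)) {
    # degenerate covariance: refit under a conjugate prior (regularized)
    pr <- mclust::priorControl()
    f1 <- fit(1, pr); f2 <- fit(2, pr)
  }
  list(f1 = f1, f2 = f2,
       bic1 = if (!is.null(f1)) f1$bic else NA_real_,
       bic2 = if (!is.null(f2)) f2$bic else NA_real_)
}

#' Recursive Gaussian-mixture clustering of a joint embedding
#'
#' At each tree node, fits 1- and 2-component Gaussian mixtures (full
#' covariances) to the member positions and splits when the Bayesian
#' information criterion prefers two components, the group holds at least
#' `min_size` members and the maximum depth is not reached. BIC ties
#' (|difference| < 1e-6) resolve to no split. Fitting uses deterministic
#' model-based hierarchical initialization, so the tree is reproducible.
#'
#' @param embedding a `joint_embedding` or a numeric position matrix with
#'   rownames.
#' @param max_depth maximum tree depth (default 8).
#' @param min_size smallest group that may be split (default 32).
#' @return object of class `cluster_tree`: `labels` (leaf path per row,
#'   e.g. `"1.2.1"`), `nodes` (data.frame of per-node decisions: path,
#'   depth, size, BICs, split), `max_depth`, `min_size`.
#' @export
recursive_gmm_cluster <- function(embedding, max_depth = 8, min_size = 32) {
  X <- if (inherits(embedding, "joint_embedding")) embedding$pair_positions
       else as.matrix(embedding)
  stopifnot(all(is.finite(X)))
  labels <- stats::setNames(rep("", nrow(X)), rownames(X))
  nodes <- list()
  recurse <- function(idx, path, depth) {
    size <- length(idx)
    if (depth >= max_depth || size < min_size) {
      nodes[[length(nodes) + 1L]] <<- data.frame(
        path = path, depth = depth, size = size, bic1 = NA_real_,
        bic2 = NA_real_, split = FALSE)
      return(invisible())
    }
    fits <- fit_gmm_pair(X[idx, , drop = FALSE])
    do_split <- !is.na(fits$bic1) && !is.na(fits$bic2) &&
      (fits$bic2 - fits$bic1) > 1e-6
    nodes[[length(nodes) + 1L]] <<- data.frame(
      path = path, depth = depth, size = size, bic1 = fits$bic1,
      bic2 = fits$bic2, split = do_split)
    if (!do_split) return(invisible())
    cls <- fits$f2$classification
    for (k in 1:2) {
      sub <- idx[cls == k]
      lab <- if (path == "") as.character(k) else paste(path, k, sep = ".")
      labels[sub] <<- lab
      recurse(sub, lab, depth + 1L)
    }
  }
  labels[] <- "root"
  recurse(seq_len(nrow(X)), "", 0L)
  labels[labels == ""] <- "root"
  structure(list(labels = labels, nodes = do.call(rbind, nodes),
                 max_depth = max_depth, min_size = min_size),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(unique(x$labels)), "leaf clusters over",
      length(x$labels), "pairs (max depth", x$max_depth,
      ", min split size", x$min_size, ")\n")
  invisible(x)
}

#' Cut a cluster tree at a given depth
#'
#' Returns the partition of the tree's members at `depth` levels below the
#' root, by truncating each leaf's label path. The tree is multiresolution:
#' shallow cuts give coarse neuron groups, the full leaf labels the finest
#' types.
#'
#' @param tree a `cluster_tree`.
#' @param depth level at which to cut (1 = first split).
#' @return named character vector of labels.
#' @export
cut_tree <- function(tree, depth) {
  stopifnot(inherits(tree, "cluster_tree"), depth >= 1)
  vapply(tree$labels, function(lab) {
    parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
    paste(parts[seq_len(min(depth, length(parts)))], collapse = ".")
  }, character(1))
}

#' Leaf cluster labels for every node of a connectome
#'
#' Expands the per-pair leaf labels of a [recursive_gmm_cluster()] tree to
#' both homologs of each pair.
#'
#' @param tree a `cluster_tree` (labels named by left-hemisphere ids).
#' @param pairs the [pair_map()] used for the embedding.
#' @return named character vector over left and right node ids.
#' @export
cluster_labels <- function(tree, pairs) {
  lab <- tree$labels
  i <- match(names(lab), pairs$left)
  stopifnot(!anyNA(i))
  stats::setNames(rep(lab, 2), c(pairs$left[i], pairs$right[i]))
}

#' Within-cluster morphological similarity score
#'
#' Consumes an externally computed pairwise morphological similarity matrix
#' (e.g. NBLAST scores) over one hemisphere's neurons: scores are
#' symmetrized by the geometric mean of the (i,j) and (j,i) entries,
#' converted to their pairwise ranks scaled into `[0, 1]`, and each
#' cluster's score is the mean of its within-cluster pairwise values.
#' Under random cluster assignment the expected score is 0.5.
#'
#' @param sim square nonnegative similarity matrix with node ids as
#'   dimnames.
#' @param clusters named vector of cluster labels covering (a subset of)
#'   the matrix ids.
#' @return named numeric vector of per-cluster scores (`NA` for clusters
#'   with fewer than 2 members in the matrix).
#' @export
cluster_morphology_score <- function(sim, clusters) {
  sim <- as.matrix(sim)
  if (any(sim < 0)) stop("similarities must be nonnegative (geometric mean)")
  stopifnot(nrow(sim) == ncol(sim), !is.null(rownames(sim)))
  S <- sqrt(sim * t(sim))
  ut <- upper.tri(S)
  vals <- S[ut]
  R <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  R[ut] <- rank(vals, ties.method = "average") / length(vals)
  R <- R + t(R)
  ids <- rownames(S)
  out <- vapply(sort(unique(clusters)), function(cl) {
    members <- intersect(names(clusters)[clusters == cl], ids)
    if (length(members) < 2) return(NA_real_)
    i <- match(members, ids)
    M <- R[i, i]
    mean(M[upper.tri(M)])
  }, numeric(1))
  out
}

#' Bilateral cluster morphology scores
#'
#' Per-cluster [cluster_morphology_score()] computed separately in each
#' hemisphere and averaged.
#'
#' @param sim_left,sim_right per-hemisphere similarity matrices.
#' @param clusters named cluster labels over nodes of both hemispheres.
#' @return named numeric vector of averaged per-cluster scores.
#' @export
bilateral_morphology_score <- function(sim_left, sim_right, clusters) {
  l <- cluster_morphology_score(sim_left, clusters)
  r <- cluster_morphology_score(sim_right, clusters)
  cls <- union(names(l), names(r))
  out <- (ifelse(is.na(l[cls]), r[cls], l[cls]) +
            ifelse(is.na(r[cls]), l[cls], r[cls])) / 2
  stats::setNames(out, cls)
}
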