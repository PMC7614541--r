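# Independent brute-force oracles used across the suite. These deliberately
# take the slow, literal route (explicit path enumeration, double loops,
# exhaustive permutations) so they share no code path with the package.

# all-pairs path enumeration for synapse flow centrality: for every
# (presynapse, postsynapse) node pair, walk the unique tree path and count
# traversals of each (child, parent) edge, weighted by site multiplicities
brute_sfc <- function(skel) {
  n <- length(skel$id)
  ancestors <- function(v) {
    out <- v
    while (!is.na(skel$parent[v])) { v <- skel$parent[v]; out <- c(out, v) }
    out
  }
  centr <- stats::setNames(numeric(n), skel$id)
  pres <- which(skel$pre > 0); posts <- which(skel$post > 0)
  for (i in pres) for (j in posts) {
    ai <- ancestors(i); aj <- ancestors(j)
    path_children <- c(setdiff(ai, aj), setdiff(aj, ai))
    centr[path_children] <- centr[path_children] + skel$pre[i] * skel$post[j]
  }
  centr
}

random_skeleton <- function(n, seed, p_site = 0.3) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(v) sample.int(v - 1L, 1), integer(1)))
  pre <- stats::rbinom(n, 2, p_site / 2)
  post <- stats::rbinom(n, 2, p_site / 2)
  pre[1] <- 0L; post[1] <- 0L  # keep the soma synapse-free
  skeleton_tree(seq_len(n), parent, pre, post)
}

# double-loop reciprocity on binarized loopless adjacencies
brute_reciprocity <- function(S, T_) {
  n <- nrow(S)
  fwd <- 0; rec <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (S[i, j] > 0) {
      fwd <- fwd + 1
      if (T_[j, i] > 0) rec <- rec + 1
    }
  }
  if (fwd == 0) NA_real_ else rec / fwd
}

# minimum-norm least-squares solution of the signal-flow objective via SVD
# of the weighted incidence matrix (independent of the Laplacian route)
oracle_signal_flow <- function(A) {
  idx <- which(A > 0, arr.ind = TRUE)
  w <- A[idx]
  n <- nrow(A)
  M <- matrix(0, nrow(idx), n)
  for (e in seq_len(nrow(idx))) {
    M[e, idx[e, 1]] <- sqrt(w[e])
    M[e, idx[e, 2]] <- -sqrt(w[e])
  }
  y <- sqrt(w)
  s <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  z <- s$v %*% (dinv * crossprod(s$u, y))
  z <- drop(z)
  z - mean(z)
}

# exhaustive DFS enumeration of simple paths with at most max_hops edges
dfs_paths <- function(B, sources, targets, max_hops) {
  ids <- rownames(B)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) > 1 && v %in% targets)
      out[[length(out) + 1L]] <<- path
    if (length(path) - 1 >= max_hops) return(invisible())
    for (nb in ids[B[v, ] > 0]) {
      if (nb %in% path) next
      walk(c(path, nb))
    }
  }
  for (s in sources) walk(s)
  out
}

# exhaustive LAP by permutation enumeration (n <= 7)
brute_lap <- function(cost, maximize = FALSE) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  vals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  best <- if (maximize) which.max(vals) else which.min(vals)
  list(perm = perms[best, ], value = vals[best])
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# upstream/downstream sets within h hops by repeated neighbor expansion
brute_reach <- function(B, start, hops, mode = c("out", "in")) {
  mode <- match.arg(mode)
  ids <- rownames(B)
  frontier <- start
  seen <- character(0)
  for (k in seq_len(hops)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- if (mode == "out") ids[B[v, ] > 0] else ids[B[, v] > 0]
      nxt <- union(nxt, nb)
    }
    nxt <- setdiff(nxt, c(seen, start))
    seen <- union(seen, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  seen
}

random_digraph <- function(n, density, seed, weights = 1:5) {
  set.seed(seed)
  A <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  hit <- matrix(stats::runif(n * n) < density, n, n)
  diag(hit) <- FALSE
  A[hit] <- sample(weights, sum(hit), replace = TRUE)
  A
}
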