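#' Solve a linear assignment problem
#'
#' Finds the permutation minimizing (or maximizing) the total cost of a
#' one-to-one row-to-column assignment on a square cost matrix, by shortest
#' augmenting paths.
#'
#' @param cost square numeric matrix.
#' @param maximize maximize instead of minimize.
#' @return integer vector: column assigned to each row.
#' @export
solve_lap <- function(cost, maximize = FALSE) {
  cost <- as.matrix(cost)
  if (maximize) cost <- -cost
  lap_solve_cpp(cost)
}

# full-graph matched-edge agreement of a permutation (higher is better)
match_objective <- function(A, B, perm) {
  sum(A * B[perm, perm])
}

#' Seeded FAQ graph matching between hemispheres
#'
#' Matches the nodes of two adjacency matrices by approximately maximizing
#' the matched-edge agreement `sum_ij A[i,j] * B[perm(i), perm(j)]`
#' (equivalently, minimizing the norm of the difference of the permuted
#' adjacencies), using Frank-Wolfe ascent on the relaxed quadratic
#' assignment problem over doubly stochastic matrices. Seed pairs are
#' clamped to their known assignment throughout. Each random
#' initialization is a convex combination of the barycenter and a random
#' permutation; the final iterate is projected to a permutation by linear
#' assignment.
#'
#' @param a_left,a_right adjacency matrices (equal size; if unequal the
#'   smaller is padded with isolated dummy nodes, which are stripped from
#'   reported matches).
#' @param seeds 2-column matrix of known (left id, right id) pairs, or
#'   `NULL` for unseeded matching.
#' @param n_init number of random initializations (default 50).
#' @param max_iter maximum Frank-Wolfe iterations per run (default 30).
#' @param seed master RNG seed.
#' @param tol convergence threshold on the step displacement.
#' @return object of class `match_runs`: a list of runs, each with
#'   `permutation` (named: left id -> right id, seeds included),
#'   `objective` (matched-edge agreement of the projected permutation),
#'   `objective_init` (agreement of the initialization's projection) and
#'   `D` (final doubly stochastic iterate over all nodes, seeds as
#'   identity), plus `left_ids`, `right_ids`.
#' @export
seeded_graph_match <- function(a_left, a_right, seeds = NULL, n_init = 50,
                               max_iter = 30, seed = 1, tol = 1e-6) {
  A <- as_adjacency(a_left); B <- as_adjacency(a_right)
  # pad the smaller side with isolated dummy nodes
  pad <- function(M, k, tag) {
    if (k == 0) return(M)
    n <- nrow(M)
    out <- matrix(0, n + k, n + k)
    out[seq_len(n), seq_len(n)] <- M
    rownames(out) <- colnames(out) <- c(rownames(M), paste0(".dummy_", tag, seq_len(k)))
    out
  }
  n_dummy_l <- max(0, nrow(B) - nrow(A)); n_dummy_r <- max(0, nrow(A) - nrow(B))
  A <- pad(A, n_dummy_l, "L"); B <- pad(B, n_dummy_r, "R")
  n <- nrow(A)
  lids <- rownames(A); rids <- rownames(B)

  if (is.null(seeds)) seeds <- matrix(character(0), 0, 2)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) > 0) {
    if (anyDuplicated(seeds[, 1]) || anyDuplicated(seeds[, 2]))
      stop("seed pairs must have distinct endpoints")
    si <- match(seeds[, 1], lids); sj <- match(seeds[, 2], rids)
    if (anyNA(si) || anyNA(sj)) stop("seed ids absent from adjacency")
  } else { si <- integer(0); sj <- integer(0) }
  s <- length(si)
  ns <- n - s
  ordl <- c(si, setdiff(seq_len(n), si))
  ordr <- c(sj, setdiff(seq_len(n), sj))
  Ao <- A[ordl, ordl]; Bo <- B[ordr, ordr]
  i1 <- seq_len(s); i2 <- s + seq_len(ns)
  A12 <- Ao[i1, i2, drop = FALSE]; A21 <- Ao[i2, i1, drop = FALSE]
  A22 <- Ao[i2, i2, drop = FALSE]
  B12 <- Bo[i1, i2, drop = FALSE]; B21 <- Bo[i2, i1, drop = FALSE]
  B22 <- Bo[i2, i2, drop = FALSE]
  lin <- A21 %*% t(B21) + t(A12) %*% B12  # constant part of the gradient

  set.seed(seed)
  runs <- vector("list", n_init)
  J <- matrix(1 / ns, ns, ns)
  for (k in seq_len(n_init)) {
    if (k == 1) {
      D <- J
    } else {
      lambda <- stats::runif(1)
      K <- diag(ns)[sample(ns), , drop = FALSE]
      D <- (1 - lambda) * J + lambda * K
    }
    obj_init <- if (ns > 0) {
      p0 <- solve_lap(D, maximize = TRUE)
      perm0 <- integer(n); perm0[ordl] <- ordr[c(seq_len(s), s + p0)]
      match_objective(A, B, perm0)
    } else match_objective(A, B, seq_len(n))
    if (ns > 0) {
      for (it in seq_len(max_iter)) {
        grad <- lin + A22 %*% D %*% t(B22) + t(A22) %*% D %*% B22
        q <- solve_lap(grad, maximize = TRUE)
        Q <- matrix(0, ns, ns); Q[cbind(seq_len(ns), q)] <- 1
        Dl <- Q - D
        u <- sum(grad * Dl)
        a2 <- sum((A22 %*% Dl %*% t(B22)) * Dl)
        alpha <- if (a2 < 0) max(0, min(1, -u / (2 * a2)))
                 else if (u + a2 > 0) 1 else 0
        step <- alpha * sqrt(sum(Dl^2))
        D <- D + alpha * Dl
        if (step < tol) break
      }
      pfin <- solve_lap(D, maximize = TRUE)
    } else pfin <- integer(0)
    # assemble the full permutation in the original index order
    perm_o <- c(seq_len(s), s + pfin)          # seed block fixed
    perm <- integer(n)
    perm[ordl] <- ordr[perm_o]
    obj <- match_objective(A, B, perm)
    Dfull <- matrix(0, n, n, dimnames = list(lids, rids))
    if (s > 0) Dfull[cbind(ordl[i1], ordr[i1])] <- 1
    if (ns > 0) Dfull[ordl[i2], ordr[i2]] <- D
    runs[[k]] <- list(
      permutation = stats::setNames(rids[perm], lids),
      objective = obj, objective_init = obj_init, D = Dfull)
  }
  structure(list(runs = runs, left_ids = lids, right_ids = rids,
                 n_seeds = s, n_dummy = c(left = n_dummy_l, right = n_dummy_r)),
            class = "match_runs")
}

#' @export
print.match_runs <- function(x, ...) {
  objs <- vapply(x$runs, `[[`, numeric(1), "objective")
  cat("match_runs:", length(x$runs), "runs on", length(x$left_ids), "nodes (",
      x$n_seeds, "seeds ); objective range",
      paste(round(range(objs), 2), collapse = " - "), "\n")
  invisible(x)
}

#' Consensus of multiple graph-matching runs
#'
#' Averages the doubly stochastic solutions of a [seeded_graph_match()]
#' collection, weighting each run by its objective value:
#' `D = (1/S) * sum_k s_k D^k` with `S = sum_k s_k`. Also tallies, per
#' (left, right) candidate pair, how often the runs' projected
#' permutations matched them.
#'
#' @param matches a `match_runs` object.
#' @return object of class `consensus_match`: `D` (weighted-average doubly
#'   stochastic matrix, dummy rows/columns removed), `votes` (match count
#'   matrix), `candidates` (per left node, right candidates ranked by
#'   consensus strength).
#' @export
match_consensus <- function(matches) {
  stopifnot(inherits(matches, "match_runs"), length(matches$runs) >= 1)
  objs <- vapply(matches$runs, `[[`, numeric(1), "objective")
  w <- objs
  if (sum(w) == 0) {
    warning("all run objectives are zero; using the unweighted average")
    w <- rep(1, length(w))
  }
  w <- w / sum(w)
  D <- Reduce(`+`, Map(function(run, wk) wk * run$D, matches$runs, w))
  votes <- matrix(0L, nrow(D), ncol(D), dimnames = dimnames(D))
  for (run in matches$runs) {
    p <- run$permutation
    votes[cbind(names(p), unname(p))] <- votes[cbind(names(p), unname(p))] + 1L
  }
  real_l <- !startsWith(rownames(D), ".dummy_")
  real_r <- !startsWith(colnames(D), ".dummy_")
  D <- D[real_l, real_r, drop = FALSE]
  votes <- votes[real_l, real_r, drop = FALSE]
  candidates <- lapply(rownames(D), function(i) {
    ord <- order(D[i, ], decreasing = TRUE)
    data.frame(left = i, right = colnames(D)[ord], strength = D[i, ord],
               votes = votes[i, ord], row.names = NULL)
  })
  structure(list(D = D, votes = votes,
                 candidates = do.call(rbind, lapply(candidates, utils::head, 5))),
            class = "consensus_match")
}

#' @export
print.consensus_match <- function(x, ...) {
  cat("consensus_match:", nrow(x$D), "x", ncol(x$D), "consensus matrix\n")
  invisible(x)
}

#' Neighbor rank of the true partner in a consensus matching
#'
#' For each known homolog pair, ranks the entries of the left neuron's row
#' of the consensus matrix in decreasing order (average ranks for ties) and
#' reports the rank of its true right partner: rank 1 means the matcher's
#' strongest candidate is the true homolog.
#'
#' @param consensus a `consensus_match` (or a matrix with id dimnames).
#' @param true_pairs a [pair_map()] or 2-column matrix of (left, right) ids.
#' @return data.frame: left, right, rank.
#' @export
neighbor_ranks <- function(consensus, true_pairs) {
  D <- if (inherits(consensus, "consensus_match")) consensus$D else as.matrix(consensus)
  if (inherits(true_pairs, "pair_map"))
    true_pairs <- cbind(true_pairs$left, true_pairs$right)
  true_pairs <- as.matrix(true_pairs)
  keep <- true_pairs[, 1] %in% rownames(D) & true_pairs[, 2] %in% colnames(D)
  true_pairs <- true_pairs[keep, , drop = FALSE]
  rk <- vapply(seq_len(nrow(true_pairs)), function(e) {
    row <- D[true_pairs[e, 1], ]
    r <- rank(-row, ties.method = "average")
    unname(r[true_pairs[e, 2]])
  }, numeric(1))
  data.frame(left = true_pairs[, 1], right = true_pairs[, 2], rank = rk,
             stringsAsFactors = FALSE, row.names = NULL)
}
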