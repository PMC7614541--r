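#' Signal-flow scores ordering a network from inputs to outputs
#'
#' Assigns each neuron a one-dimensional score such that synaptically
#' connected neurons prefer to sit one level apart, with presynaptic
#' partners above postsynaptic ones: the scores minimize
#' `sum_ij w_ij (z_i - z_j - 1)^2`. High scores indicate proximity to the
#' network's inputs, low scores to its outputs. The minimizer solves the
#' normal equations `L z = b` with `L` the Laplacian of the symmetrized
#' weight matrix and `b` the out-minus-in strength; the minimum-norm
#' solution is taken via the pseudo-inverse, and scores are reported
#' mean-centered (the objective is invariant to adding a constant).
#'
#' @param graph connectome, `thresholded_graph`, or weighted adjacency
#'   matrix; for a connectome, `type` may be any layer or `"sum"`.
#' @param type layer selector (default `"sum"`, the graph of all connection
#'   types combined).
#' @return list of class `signal_flow`: `scores` (named, mean-centered over
#'   scored nodes; `NA` for isolated nodes, which are excluded and
#'   reported), `isolated` (ids).
#' @export
signal_flow <- function(graph, type = "sum") {
  A <- as_adjacency(graph, type)
  if (nrow(A) == 0) stop("empty graph")
  diag(A) <- 0
  deg <- rowSums(A) + colSums(A)
  iso <- deg == 0
  ids <- rownames(A)
  if (all(iso)) stop("graph has no edges")
  W <- A[!iso, !iso, drop = FALSE]
  L <- diag(rowSums(W) + colSums(W)) - (W + t(W))
  b <- rowSums(W) - colSums(W)
  z <- drop(MASS::ginv(L) %*% b)
  z <- z - mean(z)
  scores <- stats::setNames(rep(NA_real_, length(ids)), ids)
  scores[!iso] <- z
  structure(list(scores = scores, isolated = ids[iso]), class = "signal_flow")
}

#' @export
print.signal_flow <- function(x, ...) {
  cat("signal_flow:", sum(!is.na(x$scores)), "scored nodes,",
      length(x$isolated), "isolated\n")
  invisible(x)
}

# accept either a signal_flow object or a named numeric vector
flow_scores <- function(scores) {
  if (inherits(scores, "signal_flow")) scores$scores else scores
}

#' Rank correlation between two signal-flow sortings
#'
#' Spearman's rho between two score vectors over their shared nodes, with
#' average ranks for ties.
#'
#' @param scores_a,scores_b `signal_flow` objects or named numeric vectors.
#' @return Spearman's rho in `[-1, 1]`; `NA` with a warning when fewer than
#'   3 shared scored nodes exist.
#' @export
sorting_correlation <- function(scores_a, scores_b) {
  a <- flow_scores(scores_a); b <- flow_scores(scores_b)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 3) {
    warning("fewer than 3 shared nodes; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[shared], b[shared], method = "spearman")
}

#' Classify edges as feedforward or feedback from signal-flow scores
#'
#' An edge `i -> j` is feedforward when its source scores higher than its
#' target (`z_i > z_j`, i.e. the edge points from the sensory periphery
#' toward the outputs), feedback when `z_i < z_j`, and a tie when equal.
#' Fractions are reported both per edge and weighted by synapse count.
#'
#' @param graph connectome or adjacency matrix.
#' @param scores a `signal_flow` object or named score vector covering the
#'   edge endpoints.
#' @param type layer selector.
#' @param tie_tol score differences below this magnitude count as ties
#'   (exchangeable nodes get equal scores only up to numerical precision).
#' @return list: `edges` (pre, post, weight, direction),
#'   `synapse_fractions` and `edge_fractions` (named feedforward / feedback
#'   / tie).
#' @export
classify_edge_direction <- function(graph, scores, type = "ad",
                                    tie_tol = 1e-9) {
  A <- as_adjacency(graph, type)
  z <- flow_scores(scores)
  idx <- which(A > 0, arr.ind = TRUE)
  ids <- rownames(A)
  zi <- z[ids[idx[, 1]]]; zj <- z[ids[idx[, 2]]]
  if (anyNA(zi) || anyNA(zj)) stop("scores must cover all edge endpoints")
  dir <- ifelse(abs(zi - zj) <= tie_tol, "tie",
                ifelse(zi > zj, "feedforward", "feedback"))
  w <- A[idx]
  frac_of <- function(x) {
    out <- tapply(x, factor(dir, levels = c("feedforward", "feedback", "tie")), sum)
    out[is.na(out)] <- 0
    out / sum(x)
  }
  list(
    edges = data.frame(pre = ids[idx[, 1]], post = ids[idx[, 2]], weight = w,
                       direction = dir, stringsAsFactors = FALSE),
    synapse_fractions = frac_of(w),
    edge_fractions = frac_of(rep(1, length(w)))
  )
}

#' Mean signal-flow score per group
#'
#' Group-level sorting uses the mean score of member neurons; groups are
#' returned in decreasing score order (inputs first).
#'
#' @param scores `signal_flow` object or named vector.
#' @param groups named vector of group labels (names = node ids).
#' @return named numeric vector of group means, sorted decreasing.
#' @export
group_signal_flow <- function(scores, groups) {
  z <- flow_scores(scores)
  shared <- intersect(names(z)[!is.na(z)], names(groups))
  means <- tapply(z[shared], groups[shared], mean)
  sort(means, decreasing = TRUE)
}
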