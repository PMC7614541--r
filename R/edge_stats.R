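#' Per-edge dendritic input fractions
#'
#' Normalizes each edge of a layer by the total in-weight of its target in
#' that layer. For the default a-d layer this is the fraction of the
#' target's total dendritic input contributed by the edge; columns of nodes
#' with zero input are undefined (`NaN`) and marked absent.
#'
#' @param graph a `multiplex_connectome` or adjacency matrix.
#' @param type layer to normalize (default `"ad"`).
#' @return dense matrix of fractions; defined columns sum to 1.
#' @export
input_fractions <- function(graph, type = "ad") {
  A <- as_adjacency(graph, type)
  tot <- colSums(A)
  F <- sweep(A, 2, tot, "/")  # zero-input columns become NaN
  F
}

#' Bilateral reproducibility threshold
#'
#' Retains an edge only when it is observed between homologous partners in
#' both hemispheres and the mean of the two input fractions is at least
#' `threshold`. A connection below threshold on one side is retained when
#' the opposite side compensates (e.g. 0.5% and 2% average to 1.25%, which
#' passes a 1% threshold). Edges involving unpaired nodes are exempt from
#' the both-hemispheres requirement and retained when their own fraction
#' passes.
#'
#' @param graph a `multiplex_connectome` or adjacency matrix.
#' @param pairs a [pair_map()] covering the paired nodes.
#' @param threshold minimum mean input fraction (default 0.01).
#' @param type layer to threshold; the denominator is that layer's total
#'   in-weight per target.
#' @return object of class `thresholded_graph`: `edges` (data.frame with
#'   per-side fractions), `adjacency` (retained weights), `nodes`,
#'   `threshold`, `type`.
#' @export
symmetric_threshold <- function(graph, pairs, threshold = 0.01, type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  F <- input_fractions(A)
  partner <- pair_partner(pairs, ids)
  idx <- which(A > 0, arr.ind = TRUE)
  pre <- ids[idx[, 1]]; post <- ids[idx[, 2]]
  frac <- F[idx]
  m_pre <- partner[idx[, 1]]; m_post <- partner[idx[, 2]]
  paired <- !is.na(m_pre) & !is.na(m_post)
  mi <- match(m_pre, ids); mj <- match(m_post, ids)
  mirror_w <- ifelse(paired, A[cbind(mi, mj)], NA_real_)
  mirror_f <- ifelse(paired & mirror_w > 0, F[cbind(mi, mj)], NA_real_)
  mean_f <- ifelse(paired, (frac + ifelse(is.na(mirror_f), 0, mirror_f)) / 2, frac)
  retained <- ifelse(paired,
                     !is.na(mirror_f) & mirror_f > 0 & mean_f >= threshold,
                     frac >= threshold)
  edges <- data.frame(
    pre = pre, post = post, weight = A[idx], fraction = frac,
    mirror_fraction = mirror_f, mean_fraction = mean_f,
    retained = retained, stringsAsFactors = FALSE
  )
  keep <- edges[edges$retained, , drop = FALSE]
  Athr <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  if (nrow(keep) > 0)
    Athr[cbind(match(keep$pre, ids), match(keep$post, ids))] <- keep$weight
  structure(list(edges = keep, all_edges = edges, adjacency = Athr,
                 nodes = ids, threshold = threshold, type = type),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf(
    "thresholded_graph (%s, >= %.2g%% bilateral): %d of %d edges retained\n",
    x$type, 100 * x$threshold, nrow(x$edges), nrow(x$all_edges)))
  invisible(x)
}

#' Edge-weight distribution summaries
#'
#' Summarizes the skew of a layer's weights: the fraction of weak edges
#' (1-2 synapses), of strong edges (>= `strong_min` synapses), and the share
#' of all synapses each class carries.
#'
#' @param graph connectome or adjacency matrix.
#' @param type layer name.
#' @param strong_min weight at which an edge counts as strong (default 5).
#' @return list with `histogram` (table of weights), `weak_edge_fraction`,
#'   `strong_edge_fraction`, `weak_synapse_share`, `strong_synapse_share`,
#'   `n_edges`. All summaries are `NA` for an empty layer.
#' @export
weight_distribution <- function(graph, type = "ad", strong_min = 5) {
  A <- as_adjacency(graph, type)
  w <- A[A > 0]
  if (length(w) == 0)
    return(list(histogram = table(numeric(0)), weak_edge_fraction = NA_real_,
                strong_edge_fraction = NA_real_, weak_synapse_share = NA_real_,
                strong_synapse_share = NA_real_, n_edges = 0L))
  list(
    histogram = table(w),
    weak_edge_fraction = mean(w <= 2),
    strong_edge_fraction = mean(w >= strong_min),
    weak_synapse_share = sum(w[w <= 2]) / sum(w),
    strong_synapse_share = sum(w[w >= strong_min]) / sum(w),
    n_edges = length(w)
  )
}

#' Multigraph edge reciprocity
#'
#' The conditional probability of observing the reverse edge in the target
#' layer given a forward edge in the source layer:
#' `r = sum_ij A_src[i,j] * A_tgt[j,i] / sum_ij A_src[i,j]` on the
#' unweighted, loopless adjacencies.
#'
#' @param a_source,a_target adjacency matrices (weights are binarized;
#'   diagonals ignored) over the same node set.
#' @return reciprocity in `[0, 1]`, or `NA` when the source layer is empty.
#' @export
edge_reciprocity <- function(a_source, a_target) {
  S <- as_adjacency(a_source); T_ <- as_adjacency(a_target)
  stopifnot(all(dim(S) == dim(T_)))
  S <- (S > 0) * 1; T_ <- (T_ > 0) * 1
  diag(S) <- 0; diag(T_) <- 0
  denom <- sum(S)
  if (denom == 0) return(NA_real_)
  sum(S * t(T_)) / denom
}

#' Expected multiplex overlap counts under the independent-layer null model
#'
#' Models each connection-type layer as an independent Erdos-Renyi graph
#' with global density `p[k]` and returns the expected number of ordered
#' node pairs exhibiting each of the 16 on/off patterns over the four types:
#' `m(x) = n^2 * prod_k p_k^x_k (1 - p_k)^(1 - x_k)`. The expectations sum
#' to `n^2` exactly.
#'
#' @param n node count.
#' @param p length-4 density vector in the order a-d, a-a, d-a, d-d.
#' @return data.frame with the 16 binary patterns and `expected` counts.
#' @export
expected_overlap_counts <- function(n, p) {
  stopifnot(length(p) == 4, all(p >= 0 & p <= 1))
  pat <- as.matrix(expand.grid(ad = 0:1, aa = 0:1, da = 0:1, dd = 0:1))
  expected <- apply(pat, 1, function(x) n^2 * prod(ifelse(x == 1, p, 1 - p)))
  data.frame(pat, expected = expected)
}

#' Observed multiplex overlap counts
#'
#' Counts, over all ordered node pairs, the occurrence of each combination
#' of the four connection types, and pairs them with the null-model
#' expectation computed from the realized layer densities
#' `p_k = sum(A^(k)) / n^2` (binarized adjacencies).
#'
#' @param connectome a `multiplex_connectome`.
#' @return data.frame of 16 patterns with `observed` and `expected` counts;
#'   observed counts (including the all-zero pattern) sum to `n^2`.
#' @export
observed_overlap_counts <- function(connectome) {
  stopifnot(inherits(connectome, "multiplex_connectome"))
  n <- length(connectome$nodes)
  bin <- lapply(OVERLAP_ORDER, function(ty)
    as.matrix(connectome$layers[[ty]] > 0) * 1)
  names(bin) <- OVERLAP_ORDER
  code <- bin$ad + 2 * bin$aa + 4 * bin$da + 8 * bin$dd
  counts <- tabulate(as.vector(code) + 1L, nbins = 16L)
  p <- vapply(bin, function(B) sum(B) / n^2, numeric(1))
  out <- expected_overlap_counts(n, p)
  codes <- out$ad + 2 * out$aa + 4 * out$da + 8 * out$dd
  out$observed <- counts[codes + 1L]
  out[, c("ad", "aa", "da", "dd", "observed", "expected")]
}
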