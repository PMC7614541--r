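as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed")
}

#' Degree threshold from network statistics
#'
#' The hub degree threshold used on the thresholded network: the mean of
#' the degree sequence plus `k` standard deviations.
#'
#' @param degrees numeric degree sequence.
#' @param k multiplier on the standard deviation (default 1.5).
#' @return numeric threshold.
#' @export
degree_threshold_from_stats <- function(degrees, k = 1.5) {
  mean(degrees) + k * stats::sd(degrees)
}

#' Hub classification
#'
#' Labels each node of a (typically thresholded) graph by whether its
#' number of distinct presynaptic / postsynaptic partners reaches the in-
#' and out-degree thresholds: `in` (in-hub), `out` (out-hub), `in-out`
#' (both, thresholds inclusive) or `none`. Degrees count distinct
#' partners, not synapses.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param in_thresh,out_thresh inclusive degree thresholds (default 20,
#'   the network mean plus 1.5 standard deviations in a typical insect
#'   brain a-d graph; see [degree_threshold_from_stats()]).
#' @param type layer selector.
#' @return data.frame: node, in_degree, out_degree, class.
#' @export
hub_classification <- function(graph, in_thresh = 20, out_thresh = 20,
                               type = "ad") {
  A <- as_adjacency(graph, type)
  B <- (A > 0) * 1
  diag(B) <- 0
  indeg <- colSums(B); outdeg <- rowSums(B)
  cls <- ifelse(indeg >= in_thresh & outdeg >= out_thresh, "in-out",
                ifelse(indeg >= in_thresh, "in",
                       ifelse(outdeg >= out_thresh, "out", "none")))
  data.frame(node = rownames(A), in_degree = indeg, out_degree = outdeg,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Sensory orders downstream of each input modality
#'
#' Breadth-first hop counts from each modality's input set: a direct
#' target of an input neuron is 2nd order, its targets 3rd order, and so
#' on. The overall order of a neuron is defined by its lowest-order input
#' from any modality (`1 + `minimum hop count). Neurons unreachable from
#' every input set are uncategorized (`NA`), as are neurons flagged as
#' receiving only unknown-modality input.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param input_sets named list: modality -> character vector of input
#'   node ids.
#' @param exclude node ids to leave uncategorized (e.g. neurons whose only
#'   input is of unknown modality).
#' @param type layer selector.
#' @return list: `orders` (data.frame node, order), `hops` (node x
#'   modality minimum hop matrix, `Inf` when unreachable).
#' @export
sensory_orders <- function(graph, input_sets, exclude = character(0),
                           type = "ad") {
  stopifnot(length(input_sets) >= 1, !is.null(names(input_sets)))
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  g <- as_igraph(A)
  hops <- sapply(names(input_sets), function(m) {
    src <- intersect(input_sets[[m]], ids)
    if (length(src) == 0) return(rep(Inf, length(ids)))
    d <- igraph::distances(g, v = src, to = igraph::V(g), mode = "out")
    apply(d, 2, min)
  })
  rownames(hops) <- ids
  minhop <- apply(hops, 1, min)
  order <- ifelse(is.finite(minhop), 1 + minhop, NA_real_)
  order[ids %in% exclude] <- NA_real_
  list(orders = data.frame(node = ids, order = order,
                           stringsAsFactors = FALSE, row.names = NULL),
       hops = hops)
}

#' Local neuron classification
#'
#' Classifies neurons by how confined their strong connectivity is to the
#' sensory processing layers (per-modality hop strata downstream of the
#' inputs). A type 1 local neuron sends a strict majority of its output
#' synapses to members of its own sensory layer or of the layer directly
#' upstream (same modality, one hop lower). A type 2 local neuron both
#' receives a strict majority of its input from and sends a strict
#' majority of its output to one layer it does not belong to. Remaining
#' 2nd-order neurons (direct targets of the inputs) are projection neurons
#' by exclusion; everything else is non-LN. Input and output neurons are
#' left unclassified.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param sensory a [sensory_orders()] result for the same graph.
#' @param inputs character vector of input node ids (excluded, and used
#'   for the PN definition).
#' @param outputs character vector of output node ids (excluded).
#' @param type layer selector.
#' @return data.frame: node, class in `type1_LN` / `type2_LN` / `PN` /
#'   `non-LN` / `input` / `output` / `uncategorized`.
#' @export
local_neuron_classification <- function(graph, sensory, inputs = character(0),
                                        outputs = character(0), type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  hops <- sensory$hops
  mods <- colnames(hops)
  layer_members <- function(m, h) ids[is.finite(hops[, m]) & hops[, m] == h]
  out_w <- rowSums(A); in_w <- colSums(A)

  cls <- rep("non-LN", length(ids)); names(cls) <- ids
  cls[ids %in% inputs] <- "input"; cls[ids %in% outputs] <- "output"
  overall <- sensory$orders$order[match(ids, sensory$orders$node)]
  cls[is.na(overall) & !(ids %in% c(inputs, outputs))] <- "uncategorized"

  for (v in ids[cls == "non-LN"]) {
    # type 1: majority of output into own layer or the layer directly
    # upstream, for some modality the neuron belongs to
    t1 <- FALSE
    for (m in mods) {
      h <- hops[v, m]
      if (!is.finite(h) || h < 1) next
      tgt <- union(layer_members(m, h), layer_members(m, h - 1))
      tgt <- setdiff(tgt, v)
      if (out_w[v] > 0 && sum(A[v, tgt]) > 0.5 * out_w[v]) { t1 <- TRUE; break }
    }
    if (t1) { cls[v] <- "type1_LN"; next }
    # type 2: majority input AND output to one layer the neuron is outside of
    t2 <- FALSE
    for (m in mods) {
      hs <- sort(unique(hops[is.finite(hops[, m]), m]))
      for (h in hs) {
        if (is.finite(hops[v, m]) && hops[v, m] == h) next  # own layer
        mem <- setdiff(layer_members(m, h), v)
        if (length(mem) == 0) next
        if (in_w[v] > 0 && out_w[v] > 0 &&
            sum(A[mem, v]) > 0.5 * in_w[v] && sum(A[v, mem]) > 0.5 * out_w[v]) {
          t2 <- TRUE; break
        }
      }
      if (t2) break
    }
    if (t2) { cls[v] <- "type2_LN"; next }
    if (!is.na(overall[match(v, ids)]) && overall[match(v, ids)] == 2)
      cls[v] <- "PN"
  }
  data.frame(node = ids, class = unname(cls), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Enumerate simple pathways from sources to targets
#'
#' All simple directed paths from any source to any target with at most
#' `max_hops` edges. When the total exceeds `sample_cap`, a uniform random
#' sample of that size is returned together with the exact total count.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param sources,targets disjoint character vectors of node ids.
#' @param max_hops maximum number of edges per path (default 6).
#' @param sample_cap maximum number of paths to return (default all).
#' @param seed RNG seed for the subsample.
#' @param type layer selector.
#' @return list: `paths` (list of node-id vectors), `total_count`.
#' @export
enumerate_pathways <- function(graph, sources, targets, max_hops = 6,
                               sample_cap = Inf, seed = 1, type = "ad") {
  if (length(intersect(sources, targets)) > 0)
    stop("sources and targets must be disjoint")
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  sources <- intersect(sources, ids); targets <- intersect(targets, ids)
  g <- as_igraph(A)
  paths <- list()
  for (s in sources) {
    ps <- igraph::all_simple_paths(g, from = s, to = targets,
                                   mode = "out", cutoff = max_hops)
    paths <- c(paths, lapply(ps, function(p) ids[as.integer(p)]))
  }
  # keep only paths whose endpoint is a target (all_simple_paths guarantees
  # this, but be defensive about degenerate 0-length paths)
  paths <- Filter(function(p) length(p) >= 2 && p[length(p)] %in% targets, paths)
  total <- length(paths)
  if (total > sample_cap) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    paths <- paths[sample.int(total, sample_cap)]
  }
  list(paths = paths, total_count = total)
}

#' Contralateral presynaptic-site fraction per neuron
#'
#' The fraction of each neuron's presynaptic sites (outgoing synapses,
#' weighted by count) that target the opposite hemisphere. Neurons with no
#' presynaptic sites are `NA`.
#'
#' @param connectome a `multiplex_connectome` with hemisphere metadata.
#' @param type layer selector (default `"ad"`).
#' @return named numeric vector in `[0, 1]`.
#' @export
contralateral_fraction <- function(connectome, type = "ad") {
  stopifnot(inherits(connectome, "multiplex_connectome"))
  A <- as_adjacency(connectome, type)
  hemi <- connectome$meta$hemisphere
  opp <- outer(hemi, hemi, function(a, b)
    (a == "left" & b == "right") | (a == "right" & b == "left"))
  tot <- rowSums(A)
  ifelse(tot > 0, rowSums(A * opp) / tot, NA_real_)
}

#' Axon laterality classes
#'
#' Classifies each neuron as ipsilateral, bilateral or contralateral from
#' its contralateral presynaptic-site fraction. The cutoffs are
#' conventions (the underlying distribution is strongly trimodal in real
#' brains) and configurable.
#'
#' @param fraction numeric vector from [contralateral_fraction()].
#' @param low at or below: ipsilateral (default 0.2).
#' @param high at or above: contralateral (default 0.8).
#' @return character vector (`NA` stays `NA`, i.e. unlabeled).
#' @export
axon_laterality <- function(fraction, low = 0.2, high = 0.8) {
  ifelse(is.na(fraction), NA_character_,
         ifelse(fraction >= high, "contralateral",
                ifelse(fraction <= low, "ipsilateral", "bilateral")))
}

#' Cosine similarity of a bilateral neuron's partners across hemispheres
#'
#' For a neuron projecting to both hemispheres, builds its ipsilateral and
#' contralateral output vectors indexed by homolog-pair identity and
#' returns their cosine similarity: 1 when it targets the same homologs
#' with the same weights on both sides, 0 when the partner sets are
#' disjoint.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param pairs a [pair_map()].
#' @param neuron node id.
#' @param hemisphere_of named vector node -> hemisphere; inferred from the
#'   connectome metadata when `graph` is a `multiplex_connectome`.
#' @param type layer selector.
#' @return cosine in `[0, 1]`, `NA` when either output vector is zero.
#' @export
bilateral_partner_similarity <- function(graph, pairs, neuron,
                                         hemisphere_of = NULL, type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  if (is.null(hemisphere_of)) {
    if (!inherits(graph, "multiplex_connectome"))
      stop("hemisphere_of required unless graph is a multiplex_connectome")
    hemisphere_of <- stats::setNames(graph$meta$hemisphere, graph$meta$node_id)
  }
  stopifnot(neuron %in% ids)
  own <- hemisphere_of[neuron]
  if (!own %in% c("left", "right")) stop("neuron must have a hemisphere")
  out_w <- A[neuron, ]
  tgt_h <- hemisphere_of[ids]
  m <- length(pairs$left)
  vec <- function(side) {
    w <- out_w[tgt_h == side]
    keep <- names(w)[w > 0]
    v <- numeric(m)
    pid <- ifelse(keep %in% pairs$left, match(keep, pairs$left),
                  match(keep, pairs$right))
    ok <- !is.na(pid)
    v[pid[ok]] <- w[keep][ok]
    v
  }
  vi <- vec(own)
  vc <- vec(if (own == "left") "right" else "left")
  if (sum(vi) == 0 || sum(vc) == 0) return(NA_real_)
  sum(vi * vc) / sqrt(sum(vi^2) * sum(vc^2))
}

#' Reciprocal loops between homologous contralateral partners
#'
#' A pair loop is a homolog pair (L, R) with direct edges in both
#' directions (L to R and R to L). Pair loops linked by edges between
#' their member neurons form double loops (components of two pair loops)
#' or super loops (three or more).
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param pairs a [pair_map()].
#' @param type layer selector.
#' @return list: `pair_loops` (data.frame left, right), `components` (list
#'   of pair-loop index vectors), `double_loops`, `super_loops` (counts).
#' @export
homolog_reciprocal_loops <- function(graph, pairs, type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  keep <- pairs$left %in% ids & pairs$right %in% ids
  l <- pairs$left[keep]; r <- pairs$right[keep]
  li <- match(l, ids); ri <- match(r, ids)
  isloop <- A[cbind(li, ri)] > 0 & A[cbind(ri, li)] > 0
  loops <- data.frame(left = l[isloop], right = r[isloop],
                      stringsAsFactors = FALSE)
  k <- nrow(loops)
  if (k == 0)
    return(list(pair_loops = loops, components = list(),
                double_loops = 0L, super_loops = 0L))
  # link pair loops sharing any inter-pair edge between their members
  linked <- matrix(FALSE, k, k)
  mem <- lapply(seq_len(k), function(i)
    match(c(loops$left[i], loops$right[i]), ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    linked[i, j] <- any(A[mem[[i]], mem[[j]]] > 0)
  }
  g <- igraph::graph_from_adjacency_matrix(linked | t(linked), mode = "undirected")
  comp <- igraph::components(g)
  comps <- split(seq_len(k), comp$membership)
  sizes <- lengths(comps)
  list(pair_loops = loops, components = unname(comps[sizes >= 2]),
       double_loops = sum(sizes == 2), super_loops = sum(sizes >= 3))
}

#' Connection probability between groups
#'
#' The fraction of possible ordered cross-group node pairs realized as
#' edges; within a group, self-pairs are excluded.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param groups named vector of group labels (names = node ids).
#' @param type layer selector.
#' @return group x group probability matrix (`NaN` rows/columns for empty
#'   groups).
#' @export
group_connection_probability <- function(graph, groups, type = "ad") {
  A <- as_adjacency(graph, type)
  B <- (A > 0) * 1
  diag(B) <- 0
  ids <- rownames(A)
  groups <- groups[names(groups) %in% ids]
  gl <- sort(unique(groups))
  M <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  for (a in gl) for (b in gl) {
    ia <- match(names(groups)[groups == a], ids)
    ib <- match(names(groups)[groups == b], ids)
    poss <- if (a == b) length(ia) * (length(ia) - 1) else length(ia) * length(ib)
    M[a, b] <- if (poss > 0) sum(B[ia, ib]) / poss else NaN
  }
  M
}

#' Zigzag motifs between descending and ascending neurons
#'
#' Finds zigzag motifs DN1 -> AN -> DN2 with two distinct descending
#' neurons flanking one ascending neuron. Extended variants allow each leg
#' to pass through up to one intermediate neuron (motifs of 3 to 5 nodes).
#' Reciprocal DN <-> AN loops (the same DN both upstream and downstream of
#' an AN) are searched separately and reported, never counted as zigzags.
#'
#' @param graph `thresholded_graph`, connectome or adjacency matrix.
#' @param dn_set,an_set character vectors of descending / ascending node
#'   ids (disjoint).
#' @param intermediates candidate ids for extended legs (default: all
#'   nodes outside `dn_set` and `an_set`).
#' @param max_leg maximum edges per leg: 1 = direct only (3-node motifs),
#'   2 allows one intermediate per leg (up to 5 nodes).
#' @param type layer selector.
#' @return list: `zigzags` (data.frame dn1, an, dn2, n_nodes),
#'   `reciprocal_loops` (data.frame dn, an).
#' @export
zigzag_motifs <- function(graph, dn_set, an_set, intermediates = NULL,
                          max_leg = 1, type = "ad") {
  if (length(intersect(dn_set, an_set)) > 0)
    stop("dn_set and an_set must be disjoint")
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  dn_set <- intersect(dn_set, ids); an_set <- intersect(an_set, ids)
  if (is.null(intermediates)) intermediates <- setdiff(ids, c(dn_set, an_set))
  B <- (A > 0) * 1
  # leg connectivity: direct edge, optionally via one intermediate
  leg <- function(from, to) {
    res <- (B[from, to, drop = FALSE] > 0) * 1
    if (max_leg >= 2 && length(intermediates) > 0) {
      via <- B[from, intermediates, drop = FALSE] %*%
        B[intermediates, to, drop = FALSE] > 0
      res[res == 0 & via] <- 2
    }
    res  # 0 = no leg, 1 = direct, 2 = one intermediate
  }
  down <- leg(dn_set, an_set)   # DN -> AN
  up <- leg(an_set, dn_set)     # AN -> DN
  rows <- list()
  for (a in seq_along(an_set)) {
    d_in <- dn_set[down[, a] > 0]
    d_out <- dn_set[up[a, ] > 0]
    for (d1 in d_in) for (d2 in d_out) {
      if (d1 == d2) next
      rows[[length(rows) + 1L]] <- data.frame(
        dn1 = d1, an = an_set[a], dn2 = d2,
        n_nodes = 1L + down[match(d1, dn_set), a] + up[a, match(d2, dn_set)],
        stringsAsFactors = FALSE)
    }
  }
  zz <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dn1 = character(0), an = character(0), dn2 = character(0),
               n_nodes = integer(0))
  rec <- which(B[dn_set, an_set, drop = FALSE] * t(B[an_set, dn_set, drop = FALSE]) > 0,
               arr.ind = TRUE)
  recip <- data.frame(dn = dn_set[rec[, 1]], an = an_set[rec[, 2]],
                      stringsAsFactors = FALSE)
  list(zigzags = zz, reciprocal_loops = recip)
}
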