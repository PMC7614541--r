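#' Create a rooted skeleton tree
#'
#' A neuronal arbor represented as a rooted tree: one node per skeleton
#' point, a parent pointer per node (the root is the soma), and per-node
#' presynaptic and postsynaptic site counts.
#'
#' @param node_id integer or character node identifiers (unique).
#' @param parent_id parent of each node; `NA` (or an id absent from
#'   `node_id`, e.g. `-1` in SWC files) marks the root. Exactly one root is
#'   required.
#' @param pre,post non-negative per-node presynaptic / postsynaptic site
#'   counts.
#' @return an object of class `skeleton_tree`.
#' @export
skeleton_tree <- function(node_id, parent_id, pre = 0L, post = 0L) {
  n <- length(node_id)
  if (anyDuplicated(node_id)) stop("node_id must be unique")
  id <- as.character(node_id)
  parent <- match(as.character(parent_id), id)  # NA for root
  if (sum(is.na(parent)) != 1L) stop("skeleton must have exactly one root")
  root <- which(is.na(parent))
  # verify acyclicity / connectivity by walking up from every node
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  for (v in seq_len(n)) {
    chain <- integer(0)
    u <- v
    while (is.na(depth[u])) {
      chain <- c(chain, u)
      u <- parent[u]
      if (is.na(u) || length(chain) > n) stop("skeleton contains a cycle")
    }
    if (length(chain) > 0)
      depth[chain] <- depth[u] + rev(seq_along(chain))
  }
  structure(
    list(id = id, parent = parent, root = root, depth = depth,
         pre = rep_len(as.integer(pre), n), post = rep_len(as.integer(post), n)),
    class = "skeleton_tree"
  )
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat("skeleton_tree:", length(x$id), "nodes, root =", x$id[x$root],
      "|", sum(x$pre), "presynapses,", sum(x$post), "postsynapses\n")
  invisible(x)
}

# nodes ordered root-first so every parent precedes its children
topo_order <- function(skel) order(skel$depth)

#' Synapse flow centrality and axon/dendrite split
#'
#' For every tree edge, counts the number of presynapse-to-postsynapse pairs
#' whose unique tree path traverses that edge. The contiguous
#' maximal-centrality segment whose interior is synapse-free is the linker
#' domain separating axon from dendrite; the split is placed at the most
#' proximal part of the linker, so the axon is everything distal to it and
#' the dendrite (the soma side) is everything proximal.
#'
#' Neurons with no presynapses or no postsynapses are `unpolarized`; neurons
#' with no synapses at all are `immature`. If several disjoint segments
#' attain the maximal centrality, the one closest to the soma is used.
#'
#' @param skel a [skeleton_tree()].
#' @return a list with class `compartment_split`:
#'   `polarity` (`"polarized"`, `"unpolarized"` or `"immature"`),
#'   `split_node` (id of the axon root, `NA` unless polarized),
#'   `edges` (data.frame child, parent, centrality),
#'   `compartment` (per-node `"axon"`/`"dendrite"`, named by node id),
#'   `linker` (ids of the linker-domain nodes).
#' @export
synapse_flow_centrality <- function(skel) {
  stopifnot(inherits(skel, "skeleton_tree"))
  n <- length(skel$id)
  ord <- topo_order(skel)
  total_pre <- sum(skel$pre); total_post <- sum(skel$post)

  # subtree synapse counts by reverse topological sweep
  pre_below <- skel$pre; post_below <- skel$post
  for (v in rev(ord)) {
    p <- skel$parent[v]
    if (!is.na(p)) {
      pre_below[p] <- pre_below[p] + pre_below[v]
      post_below[p] <- post_below[p] + post_below[v]
    }
  }
  child <- which(!is.na(skel$parent))
  centr <- pre_below[child] * (total_post - post_below[child]) +
    post_below[child] * (total_pre - pre_below[child])
  edges <- data.frame(child = skel$id[child], parent = skel$id[skel$parent[child]],
                      centrality = centr, stringsAsFactors = FALSE)

  done <- function(polarity, split_node = NA_character_, comp = NULL,
                   linker = character(0)) {
    structure(list(polarity = polarity, split_node = split_node,
                   edges = edges, compartment = comp, linker = linker),
              class = "compartment_split")
  }
  if (total_pre + total_post == 0L) return(done("immature"))
  if (total_pre == 0L || total_post == 0L) return(done("unpolarized"))

  m <- max(centr)
  if (m == 0) return(done("unpolarized"))
  cand <- child[centr == m]  # candidate edges, keyed by child endpoint

  # contiguous segments: connected components of the candidate-edge subgraph
  comp_id <- seq_len(n)
  find <- function(a) { while (comp_id[a] != a) a <- comp_id[a] <- comp_id[comp_id[a]]; a }
  for (v in cand) comp_id[find(v)] <- find(skel$parent[v])
  groups <- split(cand, vapply(cand, function(v) find(v), integer(1)))

  has_syn <- skel$pre + skel$post > 0L
  valid <- Filter(function(g) {
    nodes <- unique(c(g, skel$parent[g]))
    deg <- table(factor(c(g, skel$parent[g]), levels = nodes))
    interior <- as.integer(names(deg))[deg >= 2L]
    !any(has_syn[interior])
  }, groups)
  if (length(valid) == 0) return(done("unpolarized"))

  # choose segment closest to the soma, then its most proximal edge
  seg_depth <- vapply(valid, function(g) min(skel$depth[skel$parent[g]]), numeric(1))
  seg <- valid[[which.min(seg_depth)]]
  prox <- seg[which.min(skel$depth[skel$parent[seg]])]
  if (sum(skel$depth[skel$parent[seg]] == min(skel$depth[skel$parent[seg]])) > 1) {
    tied <- seg[skel$depth[skel$parent[seg]] == min(skel$depth[skel$parent[seg]])]
    prox <- tied[order(skel$id[tied])][1]  # deterministic tie-break
  }
  split_node <- prox  # axon root: child endpoint of the most proximal linker edge

  # axon = subtree of split_node; dendrite = soma side
  in_axon <- rep(FALSE, n)
  in_axon[split_node] <- TRUE
  for (v in ord) {
    p <- skel$parent[v]
    if (!is.na(p) && in_axon[p]) in_axon[v] <- TRUE
  }
  comp <- ifelse(in_axon, "axon", "dendrite")
  names(comp) <- skel$id
  linker_nodes <- unique(c(seg, skel$parent[seg]))
  done("polarized", skel$id[split_node], comp, skel$id[linker_nodes])
}

#' @export
print.compartment_split <- function(x, ...) {
  cat("compartment_split:", x$polarity)
  if (x$polarity == "polarized")
    cat(", axon root =", x$split_node,
        sprintf("(%d axon / %d dendrite nodes)", sum(x$compartment == "axon"),
                sum(x$compartment == "dendrite")))
  cat("\n")
  invisible(x)
}
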