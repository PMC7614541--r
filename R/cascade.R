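#' Specification of a signal cascade experiment
#'
#' The cascade is a modified independent-cascade model: starting from a set
#' of active neurons, every synapse from an active (non-stop) neuron to a
#' not-yet-activated neuron transmits independently with probability `p`
#' each hop; a neuron with at least one successful upstream transmission
#' activates at the next hop, and previously active neurons deactivate for
#' the rest of the run. Stop neurons can become active but do not propagate.
#'
#' @param start character vector of start node ids (active at hop 0).
#' @param stop character vector of stop node ids (may overlap `start`).
#' @param p per-synapse transmission probability (default 0.05).
#' @param max_hops maximum number of hops `T` (default 8).
#' @param iterations number of independent cascade runs (default 1000).
#' @param seed master seed; per-iteration substreams are derived from it so
#'   results are bit-reproducible.
#' @return list of class `cascade_spec`.
#' @export
cascade_spec <- function(start, stop = character(0), p = 0.05, max_hops = 8,
                         iterations = 1000, seed = 1) {
  stopifnot(p > 0, p < 1, max_hops >= 1, iterations >= 1, length(start) >= 1)
  structure(list(start = as.character(start), stop = as.character(stop),
                 p = p, max_hops = max_hops, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "cascade_spec")
}

#' Run stochastic signal cascades
#'
#' Repeats the cascade of a [cascade_spec()] and tracks, per node and hop,
#' the fraction of iterations in which the node activated at that hop, plus
#' the per-node fraction of iterations with any activation
#' (`visit_probability`). Within one iteration a node activates at most
#' once, so each row of the activation matrix sums to at most 1.
#'
#' Per-edge transmission is drawn as one event of probability
#' `1 - (1-p)^w` for an edge of weight `w`, the probability that at least
#' one of `w` independent per-synapse Bernoulli(p) trials succeeds.
#'
#' @param graph connectome, `thresholded_graph`, or weighted adjacency.
#' @param spec a [cascade_spec()].
#' @param type layer selector (default `"ad"`).
#' @return list of class `cascade_result`: `activation_probability`
#'   (node x hop matrix, hop 0 = the start state), `visit_probability`,
#'   `spec`.
#' @export
run_cascade <- function(graph, spec, type = "ad") {
  stopifnot(inherits(spec, "cascade_spec"))
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  n <- length(ids)
  s0 <- match(spec$start, ids)
  if (anyNA(s0)) stop("start nodes absent from graph: ",
                      paste(spec$start[is.na(s0)], collapse = ", "))
  stop_idx <- stats::na.omit(match(spec$stop, ids))
  is_stop <- rep(FALSE, n); is_stop[stop_idx] <- TRUE
  T_ <- spec$max_hops
  q <- 1 - spec$p

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, spec$iterations,
                           replace = TRUE)

  act_counts <- matrix(0, n, T_ + 1L)
  visit_counts <- numeric(n)
  for (it in seq_len(spec$iterations)) {
    set.seed(iter_seeds[it])
    active <- rep(FALSE, n); active[s0] <- TRUE
    ever <- active
    act_counts[s0, 1L] <- act_counts[s0, 1L] + 1
    for (t in seq_len(T_)) {
      prop <- active & !is_stop
      if (!any(prop)) break
      w_in <- colSums(A[prop, , drop = FALSE])
      prob <- 1 - q^w_in
      u <- stats::runif(n)
      newly <- !ever & (u < prob)
      active <- newly
      if (any(newly)) {
        ever <- ever | newly
        act_counts[newly, t + 1L] <- act_counts[newly, t + 1L] + 1
      }
    }
    visit_counts <- visit_counts + ever
  }
  ap <- act_counts / spec$iterations
  dimnames(ap) <- list(ids, paste0("hop", 0:T_))
  structure(list(activation_probability = ap,
                 visit_probability = stats::setNames(visit_counts / spec$iterations, ids),
                 spec = spec),
            class = "cascade_result")
}

# save/restore the global RNG state so cascade runs do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result:", nrow(x$activation_probability), "nodes,",
      ncol(x$activation_probability) - 1L, "hops,",
      x$spec$iterations, "iterations;",
      sum(x$visit_probability > 0), "nodes ever visited\n")
  invisible(x)
}

#' Which nodes receive cascade signal
#'
#' A node receives the signal when it is visited in most cascade
#' iterations, i.e. a strict majority (`visit_probability > threshold`).
#'
#' @param result a `cascade_result`.
#' @param threshold strict lower bound on the visit probability (0.5).
#' @return named logical vector.
#' @export
receives_signal <- function(result, threshold = 0.5) {
  result$visit_probability > threshold
}

#' Sensory modality integration per node
#'
#' Given one cascade per input modality, labels each node by how many
#' modalities reach it: `none`, `unimodal` (exactly one) or `multimodal`,
#' together with the combination of modalities.
#'
#' @param results named list (one `cascade_result` per modality).
#' @param threshold passed to [receives_signal()].
#' @return data.frame: node, n_modalities, label, combination.
#' @export
modality_integration <- function(results, threshold = 0.5) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  hit <- vapply(results, receives_signal, logical(length(results[[1]]$visit_probability)),
                threshold = threshold)
  nmod <- rowSums(hit)
  combo <- apply(hit, 1, function(h) paste(colnames(hit)[h], collapse = "+"))
  data.frame(
    node = rownames(hit), n_modalities = nmod,
    label = ifelse(nmod == 0, "none", ifelse(nmod == 1, "unimodal", "multimodal")),
    combination = combo, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Signal lateralization from left- and right-seeded cascades
#'
#' Quantifies each neuron's lateralization as the ratio of left to total
#' (left + right) visit probability, for cascades started from left-only
#' and right-only input sets. A neuron is `lateralized` when only one side
#' passes [receives_signal()], `integrative` when both do.
#'
#' @param left_result,right_result `cascade_result`s from left-/right-side
#'   start sets on the same graph.
#' @param threshold passed to [receives_signal()].
#' @return data.frame: node, left, right, ratio, flag in
#'   `no_signal` / `weak` / `lateralized` / `integrative`.
#' @export
lateralization <- function(left_result, right_result, threshold = 0.5) {
  l <- left_result$visit_probability
  r <- right_result$visit_probability[names(l)]
  ratio <- ifelse(l + r > 0, l / (l + r), NA_real_)
  pl <- l > threshold; pr <- r > threshold
  flag <- ifelse(l + r == 0, "no_signal",
                 ifelse(pl & pr, "integrative",
                        ifelse(pl | pr, "lateralized", "weak")))
  data.frame(node = names(l), left = l, right = r, ratio = ratio,
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

# hop-resolved cascade reach from every source node: visit[i, j] and
# hop-activation array act[i, j, t] for cascades seeded at i
cascade_reach <- function(A, hops, p, iterations, seed) {
  ids <- rownames(A)
  n <- length(ids)
  visit <- matrix(0, n, n, dimnames = list(ids, ids))
  act <- array(0, dim = c(n, n, hops + 1L))
  for (i in seq_len(n)) {
    res <- run_cascade(A, cascade_spec(ids[i], p = p, max_hops = hops,
                                       iterations = iterations,
                                       seed = seed + i))
    visit[i, ] <- res$visit_probability
    act[i, , ] <- res$activation_probability
  }
  list(visit = visit, act = act)
}

#' Recurrence of individual neurons
#'
#' The recurrence of a neuron is the fraction of its polysynaptic
#' downstream partners (nodes reached by a cascade of up to `hops` hops
#' seeded at the neuron) that send signal back to it (the neuron is reached
#' by a cascade of up to `hops` hops seeded at the partner). Also reports,
#' per neuron, the mean number of distinct return path lengths (hops at
#' which the source activates in a returning partner's cascade).
#'
#' @param graph connectome or adjacency matrix.
#' @param neurons node ids to score (default: all).
#' @param hops cascade depth (default 5).
#' @param p,iterations,seed cascade parameters.
#' @param type layer selector.
#' @param min_visit minimum visit probability for a node to count as a
#'   downstream partner / as returning signal (default 0: any visit).
#' @return data.frame: neuron, n_downstream, n_returning, recurrence
#'   (`NA` when a neuron has no downstream partners), mean_return_lengths.
#' @export
recurrence_fraction <- function(graph, neurons = NULL, hops = 5, p = 0.05,
                                iterations = 1000, seed = 1, type = "ad",
                                min_visit = 0) {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  if (is.null(neurons)) neurons <- ids
  stopifnot(all(neurons %in% ids))
  reach <- cascade_reach(A, hops, p, iterations, seed)
  res <- lapply(neurons, function(x) {
    i <- match(x, ids)
    down <- which(reach$visit[i, ] > min_visit)
    down <- setdiff(down, i)
    if (length(down) == 0)
      return(data.frame(neuron = x, n_downstream = 0L, n_returning = 0L,
                        recurrence = NA_real_, mean_return_lengths = NA_real_))
    ret <- down[reach$visit[down, i] > min_visit]
    lens <- vapply(ret, function(j) sum(reach$act[j, i, -1L] > 0), numeric(1))
    data.frame(neuron = x, n_downstream = length(down),
               n_returning = length(ret),
               recurrence = length(ret) / length(down),
               mean_return_lengths = if (length(ret)) mean(lens) else NA_real_)
  })
  do.call(rbind, res)
}

#' Cluster-to-cluster cascade signal, split forward/backward
#'
#' Starts one cascade per cluster (seeded at all its members) and records
#' the mean visit probability of every other cluster's members. Clusters
#' are ordered by decreasing mean signal-flow score (inputs first), so
#' above-diagonal entries are forward signal (toward the outputs) and
#' below-diagonal entries are backward signal.
#'
#' @param graph connectome or adjacency matrix.
#' @param clusters named vector of cluster labels (names = node ids).
#' @param scores `signal_flow` object or named scores used to order the
#'   clusters.
#' @param hops cascade depth (default 2).
#' @param p,iterations,seed cascade parameters.
#' @param type layer selector.
#' @return list: `matrix` (source x target mean visit probability, ordered
#'   inputs-to-outputs), `order` (cluster labels), `forward`, `backward`
#'   (summed off-diagonal signal).
#' @export
cluster_flow_matrix <- function(graph, clusters, scores, hops = 2, p = 0.05,
                                iterations = 1000, seed = 1, type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  clusters <- clusters[names(clusters) %in% ids]
  ord <- names(group_signal_flow(scores, clusters))
  k <- length(ord)
  M <- matrix(0, k, k, dimnames = list(ord, ord))
  for (s in seq_len(k)) {
    members <- names(clusters)[clusters == ord[s]]
    res <- run_cascade(A, cascade_spec(members, p = p, max_hops = hops,
                                       iterations = iterations, seed = seed + s),
                       type = type)
    for (t in seq_len(k)) {
      tgt <- names(clusters)[clusters == ord[t]]
      if (t == s) tgt <- setdiff(tgt, members)
      M[s, t] <- if (length(tgt)) mean(res$visit_probability[tgt]) else 0
    }
  }
  list(matrix = M, order = ord,
       forward = sum(M[upper.tri(M)]), backward = sum(M[lower.tri(M)]))
}

#' Efference-copy reach of output neurons
#'
#' For each output neuron, finds its brain partners within `hops` hops of
#' a-d connectivity and splits them into `recurrent` (the partner is itself
#' directly or indirectly upstream of the same output neuron within `hops`
#' hops) and `parallel` (upstream of other outputs only, or of none).
#'
#' @param graph connectome or adjacency matrix.
#' @param output_neurons character vector of output node ids.
#' @param hops maximum hop count (default 2).
#' @param type layer selector.
#' @return data.frame per output neuron: n_direct, n_within_hops,
#'   n_recurrent, n_parallel; plus a `partners` attribute listing each
#'   partner's classification.
#' @export
efference_copy_reach <- function(graph, output_neurons, hops = 2, type = "ad") {
  A <- as_adjacency(graph, type)
  ids <- rownames(A)
  stopifnot(all(output_neurons %in% ids))
  B <- (A > 0) * 1
  # reachability within <= hops
  reach <- B
  acc <- B
  if (hops > 1) for (k in 2:hops) { reach <- (reach %*% B > 0) * 1; acc <- ((acc + reach) > 0) * 1 }
  partner_rows <- list()
  out <- lapply(output_neurons, function(o) {
    i <- match(o, ids)
    down <- setdiff(which(acc[i, ] > 0), i)
    up <- setdiff(which(acc[, i] > 0), i)
    rec <- intersect(down, up)
    partner_rows[[o]] <<- data.frame(
      output = o, partner = ids[down],
      class = ifelse(down %in% rec, "recurrent", "parallel"),
      stringsAsFactors = FALSE)
    data.frame(output = o, n_direct = sum(B[i, ]) - B[i, i],
               n_within_hops = length(down), n_recurrent = length(rec),
               n_parallel = length(down) - length(rec))
  })
  res <- do.call(rbind, out)
  attr(res, "partners") <- do.call(rbind, partner_rows)
  res
}
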