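#' Pair map between hemispheres
#'
#' A partial bijection between left- and right-hemisphere node ids, plus the
#' set of unpaired nodes (e.g. Kenyon cells, which lack clear homologs).
#'
#' @param left,right equal-length character vectors of homologous node ids.
#' @param unpaired character vector of nodes without a homolog.
#' @return an object of class `pair_map`.
#' @export
pair_map <- function(left, right, unpaired = character(0)) {
  stopifnot(length(left) == length(right))
  if (anyDuplicated(c(left, right, unpaired)))
    stop("a node may appear in at most one pair")
  structure(list(left = as.character(left), right = as.character(right),
                 unpaired = as.character(unpaired)),
            class = "pair_map")
}

#' @export
print.pair_map <- function(x, ...) {
  cat("pair_map:", length(x$left), "homolog pairs,",
      length(x$unpaired), "unpaired\n")
  invisible(x)
}

# homolog of each id under the map (NA for unpaired/unknown)
pair_partner <- function(pairs, ids) {
  out <- rep(NA_character_, length(ids))
  i <- match(ids, pairs$left); out[!is.na(i)] <- pairs$right[i[!is.na(i)]]
  j <- match(ids, pairs$right); out[!is.na(j)] <- pairs$left[j[!is.na(j)]]
  out
}

#' Configuration for the synthetic bilateral connectome generator
#'
#' The generator emulates the gross statistical structure of an insect-brain
#' multiplex connectome: two mirrored hemispheres of homolog pairs, four
#' overlapping directed connection-type layers with skewed mostly-weak
#' integer weights, hierarchical block structure with a feedforward
#' gradient, per-neuron axon laterality (ipsi/bi/contralateral), and
#' optional planted hubs, recurrent loops and zigzag motifs with a recorded
#' ground truth.
#'
#' @param n_pairs number of homolog pairs per hemisphere.
#' @param n_unpaired number of unpaired neurons (assigned alternately to the
#'   two hemispheres; not mirrored).
#' @param n_blocks number of connectivity blocks (>= 2); block 1 holds the
#'   input neurons, the last block the output neurons.
#' @param block_connectivity base connection-probability matrix
#'   (`n_blocks x n_blocks`) for the a-d layer, or a single number for a
#'   homogeneous graph. `NULL` builds a two-level hierarchical default:
#'   within-block 0.25, sibling blocks 0.10, elsewhere 0.02.
#' @param layer_densities multipliers on `block_connectivity` for the four
#'   layers, named `ad`, `aa`, `dd`, `da`.
#' @param weak_fraction target fraction of edges with weight 1-2; weights are
#'   geometric, truncated at `max_weight`.
#' @param max_weight truncation for edge weights.
#' @param mirror_noise probability that a generated edge is present on one
#'   hemisphere only; 0 gives perfectly mirrored hemispheres.
#' @param feedforward_bias probability mass of edges pointing down the
#'   planted input-to-output order (0.5 = no bias).
#' @param laterality_probs proportions of ipsilateral / bilateral /
#'   contralateral axons per neuron (defaults follow the 61/24/15 split
#'   typical of insect brains).
#' @param n_hubs,n_recurrent_loops,n_zigzags planted structure counts.
#' @param hub_degree out-partner count given to planted hubs.
#' @param n_modalities number of sensory modalities among input neurons.
#' @param seed master RNG seed; all randomness derives from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_pairs = 100, n_unpaired = 0, n_blocks = 4,
                             block_connectivity = NULL,
                             layer_densities = c(ad = 1, aa = 0.4, dd = 0.15, da = 0.08),
                             weak_fraction = 0.66, max_weight = 30,
                             mirror_noise = 0.05, feedforward_bias = 0.8,
                             laterality_probs = c(ipsilateral = 0.61,
                                                  bilateral = 0.24,
                                                  contralateral = 0.15),
                             n_hubs = 0, n_recurrent_loops = 0, n_zigzags = 0,
                             hub_degree = 25, n_modalities = 2, seed = 1) {
  if (is.null(block_connectivity)) {
    B <- matrix(0.02, n_blocks, n_blocks)
    for (k in seq_len(n_blocks)) {
      B[k, k] <- 0.25
      sib <- if (k %% 2 == 1) k + 1 else k - 1  # sibling in the 2-level hierarchy
      if (sib >= 1 && sib <= n_blocks) B[k, sib] <- B[sib, k] <- 0.10
    }
    block_connectivity <- B
  }
  if (length(block_connectivity) == 1)
    block_connectivity <- matrix(block_connectivity, n_blocks, n_blocks)
  stopifnot(
    n_pairs >= n_blocks, n_blocks >= 2,
    all(dim(block_connectivity) == c(n_blocks, n_blocks)),
    all(block_connectivity >= 0 & block_connectivity <= 1),
    mirror_noise >= 0, mirror_noise <= 1,
    feedforward_bias >= 0, feedforward_bias <= 1,
    weak_fraction > 0, weak_fraction < 1,
    abs(sum(laterality_probs) - 1) < 1e-8
  )
  structure(as.list(environment()), class = "generator_config")
}

# truncated geometric weights with P(w in {1,2}) = weak_fraction
sample_weights <- function(n, weak_fraction, max_weight) {
  q <- sqrt(1 - weak_fraction)
  pmin(1L + stats::rgeom(n, prob = 1 - q), as.integer(max_weight))
}

#' Generate a synthetic bilateral multiplex connectome
#'
#' Samples a mirrored two-hemisphere connectome from a [generator_config()],
#' together with the ground truth used in planting. Deterministic for a
#' fixed seed.
#'
#' @param config a [generator_config()].
#' @param return_records also return the synthetic synapse table used to
#'   build the connectome (for bookkeeping tests).
#' @return a list with elements `connectome` (a `multiplex_connectome`),
#'   `truth` (pair map, per-node block/rank/laterality, planted registries,
#'   per-type synapse totals) and optionally `records`.
#' @export
generate_connectome <- function(config, return_records = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  m <- config$n_pairs; u <- config$n_unpaired
  nb <- config$n_blocks
  if (config$n_hubs + 2 * config$n_recurrent_loops > m)
    stop("more planted structures than available pairs")

  # --- entities: m homolog pairs + u unpaired singletons -------------------
  ent_block <- rep(seq_len(nb), length.out = m)[order(rep(seq_len(nb), length.out = m))]
  ent_rank <- seq_len(m)                      # planted input-to-output order
  left_id <- sprintf("L%04d", seq_len(m))
  right_id <- sprintf("R%04d", seq_len(m))
  unp_id <- if (u > 0) sprintf("U%04d", seq_len(u)) else character(0)
  unp_hemi <- if (u > 0) rep(c("left", "right"), length.out = u) else character(0)
  unp_block <- if (u > 0) rep(max(2L, nb %/% 2L), u) else integer(0)

  # cell classes: inputs in block 1 (SN with modalities + some AN),
  # outputs in the last block, a pre-output block before it
  ent_class <- rep("IN", m)
  in_ent <- which(ent_block == 1L)
  n_an <- max(1L, floor(length(in_ent) * 0.3))
  an_ent <- in_ent[seq_len(n_an)]
  sn_ent <- setdiff(in_ent, an_ent)
  ent_class[sn_ent] <- "SN"; ent_class[an_ent] <- "AN"
  out_ent <- which(ent_block == nb)
  ent_class[out_ent] <- "DN_VNC"
  if (nb >= 3) ent_class[ent_block == nb - 1L] <- "pre-DN"
  ent_modality <- rep(NA_character_, m)
  mods <- paste0("modality", seq_len(config$n_modalities))
  ent_modality[sn_ent] <- rep(mods, length.out = length(sn_ent))
  ent_modality[an_ent] <- "somatosensory"

  lat <- sample(names(config$laterality_probs), m, replace = TRUE,
                prob = config$laterality_probs)

  # --- template edge sampling over entities, per layer ---------------------
  E <- m + u  # entity count; entities m+1..E are the unpaired nodes
  blk <- c(ent_block, unp_block)
  rnk <- c(ent_rank, stats::runif(u, 1, m))
  ffb <- config$feedforward_bias
  down <- outer(rnk, rnk, `<`)
  orient <- ifelse(down, 2 * ffb, 2 * (1 - ffb))
  base <- config$block_connectivity[blk, blk]
  templates <- list()
  for (ty in LAYER_TYPES) {
    P <- pmin(base * config$layer_densities[[ty]] * orient, 0.95)
    diag(P) <- 0
    hit <- which(matrix(stats::runif(E * E), E, E) < P, arr.ind = TRUE)
    templates[[ty]] <- data.frame(
      from = hit[, 1], to = hit[, 2],
      w = sample_weights(nrow(hit), config$weak_fraction, config$max_weight)
    )
  }

  # --- planted structures (a-d layer, strong weights) ----------------------
  mid_ent <- which(ent_block > 1L & ent_block < nb)
  if (length(mid_ent) < 2) mid_ent <- seq_len(m)
  reserved <- integer(0)
  hubs <- integer(0)
  if (config$n_hubs > 0) {
    hubs <- sample(mid_ent, config$n_hubs)
    reserved <- hubs
    extra <- do.call(rbind, lapply(hubs, function(h) {
      tgt <- sample(setdiff(seq_len(m), h), config$hub_degree)
      data.frame(from = h, to = tgt, w = 8L)
    }))
    templates$ad <- rbind(templates$ad, extra)
  }
  loops <- list()
  if (config$n_recurrent_loops > 0) {
    pool <- setdiff(mid_ent, reserved)
    pick <- sample(pool, 2 * config$n_recurrent_loops)
    for (k in seq_len(config$n_recurrent_loops)) {
      x <- pick[2 * k - 1]; y <- pick[2 * k]
      templates$ad <- rbind(templates$ad,
                            data.frame(from = c(x, y), to = c(y, x), w = 20L))
      loops[[k]] <- c(x, y)
    }
    reserved <- c(reserved, pick)
  }
  zig <- NULL
  if (config$n_zigzags > 0) {
    if (length(out_ent) < 2 || length(an_ent) < 1)
      stop("zigzag planting needs >= 2 output entities and >= 1 AN")
    zig <- data.frame(
      dn1 = sample(out_ent, config$n_zigzags, replace = TRUE),
      an = sample(an_ent, config$n_zigzags, replace = TRUE),
      dn2 = NA_integer_
    )
    for (k in seq_len(config$n_zigzags))
      zig$dn2[k] <- sample(setdiff(out_ent, zig$dn1[k]), 1)
    templates$ad <- rbind(
      templates$ad,
      data.frame(from = c(zig$dn1, zig$an), to = c(zig$an, zig$dn2), w = 12L)
    )
  }

  # --- mirror templates into left/right node copies ------------------------
  node_of <- function(ent, side) {
    side <- rep_len(side, length(ent))
    out <- character(length(ent))
    up <- ent > m
    out[up] <- unp_id[ent[up] - m]
    il <- !up & side == "L"; ir <- !up & side == "R"
    out[il] <- left_id[ent[il]]
    out[ir] <- right_id[ent[ir]]
    out
  }
  rec <- vector("list", length(LAYER_TYPES))
  names(rec) <- LAYER_TYPES
  for (ty in LAYER_TYPES) {
    tpl <- templates[[ty]]
    if (nrow(tpl) == 0) next
    # aggregate duplicate template edges (planted may overlap random)
    tpl <- stats::aggregate(w ~ from + to, data = tpl, FUN = max)
    keep <- stats::runif(nrow(tpl)) >= config$mirror_noise
    side_if_dropped <- sample(c("L", "R"), nrow(tpl), replace = TRUE)
    has_unp <- tpl$from > m | tpl$to > m
    parts <- list()
    # edges touching an unpaired node live in that node's hemisphere only
    if (any(has_unp)) {
      d <- tpl[has_unp, , drop = FALSE]
      hemi <- ifelse(d$from > m, unp_hemi[pmax(d$from - m, 1L)],
                     unp_hemi[pmax(d$to - m, 1L)])
      s <- ifelse(hemi == "left", "L", "R")
      parts[[length(parts) + 1L]] <- data.frame(
        pre = node_of(d$from, s), post = node_of(d$to, s), w = d$w,
        stringsAsFactors = FALSE)
    }
    pp <- tpl[!has_unp, , drop = FALSE]
    keep_pp <- keep[!has_unp]; side_pp <- side_if_dropped[!has_unp]
    for (s in c("L", "R")) {
      o <- if (s == "L") "R" else "L"
      d <- pp[keep_pp | side_pp == s, , drop = FALSE]
      if (nrow(d) == 0) next
      lat_i <- lat[d$from]
      tgt_side <- ifelse(lat_i == "ipsilateral", s,
                         ifelse(lat_i == "contralateral", o, s))
      parts[[length(parts) + 1L]] <- data.frame(
        pre = node_of(d$from, s), post = node_of(d$to, tgt_side), w = d$w,
        stringsAsFactors = FALSE)
      bi <- d[lat_i == "bilateral", , drop = FALSE]  # second, crossing copy
      if (nrow(bi) > 0)
        parts[[length(parts) + 1L]] <- data.frame(
          pre = node_of(bi$from, s), post = node_of(bi$to, o), w = bi$w,
          stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, parts)
    d <- d[d$pre != d$post, , drop = FALSE]
    if (nrow(d) == 0) next
    d$type <- ty
    rec[[ty]] <- d
  }
  allrec <- do.call(rbind, rec)
  if (is.null(allrec) || nrow(allrec) == 0)
    stop("generator produced no edges; increase connectivity")
  site_of <- function(ch) ifelse(ch == "a", "axon", "dendrite")
  records <- synapse_table(
    pre_id = allrec$pre, post_id = allrec$post,
    pre_site = site_of(substr(allrec$type, 1, 1)),
    post_site = site_of(substr(allrec$type, 2, 2)),
    count = allrec$w
  )
  records$type <- allrec$type

  meta <- node_meta(
    node_id = c(left_id, right_id, unp_id),
    hemisphere = c(rep("left", m), rep("right", m), unp_hemi),
    cell_class = c(ent_class, ent_class, rep("KC", u)),
    modality = c(ent_modality, ent_modality, rep(NA_character_, u)),
    is_input = c(ent_class %in% c("SN", "AN"), ent_class %in% c("SN", "AN"),
                 rep(FALSE, u)),
    is_output = c(ent_class == "DN_VNC", ent_class == "DN_VNC", rep(FALSE, u))
  )
  connectome <- build_multiplex(records, meta)

  all_ids <- c(left_id, right_id, unp_id)
  truth <- list(
    pair_map = pair_map(left_id, right_id, unp_id),
    block_of = stats::setNames(c(ent_block, ent_block, unp_block), all_ids),
    rank = stats::setNames(c(ent_rank, ent_rank, rep(NA_real_, u)), all_ids),
    laterality = stats::setNames(c(lat, lat, rep(NA_character_, u)), all_ids),
    hubs = if (length(hubs)) c(left_id[hubs], right_id[hubs]) else character(0),
    recurrent_loops = lapply(loops, function(p)
      list(left = left_id[p], right = right_id[p])),
    zigzags = if (!is.null(zig)) data.frame(
      dn1 = left_id[zig$dn1], an = left_id[zig$an], dn2 = left_id[zig$dn2],
      stringsAsFactors = FALSE) else NULL,
    type_counts = tapply(records$count, records$type, sum)
  )
  out <- list(connectome = connectome, truth = truth)
  if (return_records) out$records <- records
  out
}

#' Generate a toy skeleton with a known axon/dendrite split
#'
#' Builds a rooted arbor with all postsynapses proximal and all presynapses
#' distal to a dedicated two-node synapse-free linker, so the true split
#' node (the axon root) is known by construction.
#'
#' @param n_nodes total node count (`>= n_pre + n_post + 2`).
#' @param n_pre,n_post presynapse / postsynapse counts (one per site node).
#' @param seed RNG seed used for attaching surplus synapse-free nodes.
#' @return list with `skeleton` (a [skeleton_tree()]) and `true_split`
#'   (node id where the axon begins; `NA` when `n_pre` or `n_post` is 0).
#' @export
generate_skeleton <- function(n_nodes, n_pre, n_post, seed = 1) {
  stopifnot(n_nodes >= n_pre + n_post + 2)
  set.seed(seed)
  used <- 1L + n_post + 1L + n_pre
  id <- seq_len(n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  pre <- integer(n_nodes); post <- integer(n_nodes)
  # path: soma (1) -> post chain -> synapse-free linker node -> pre chain
  for (v in 2:used) parent[v] <- v - 1L
  if (n_post > 0) post[1L + seq_len(n_post)] <- 1L
  l1 <- 1L + n_post + 1L
  if (n_pre > 0) pre[1L + n_post + 1L + seq_len(n_pre)] <- 1L
  if (n_nodes > used) {
    hosts <- which(pre + post > 0)
    if (length(hosts) == 0) hosts <- 1L
    parent[(used + 1L):n_nodes] <- sample(hosts, n_nodes - used, replace = TRUE)
  }
  skel <- skeleton_tree(id, ifelse(is.na(parent), -1L, parent), pre, post)
  true_split <- if (n_pre > 0 && n_post > 0) as.character(l1) else NA_character_
  list(skeleton = skel, true_split = true_split)
}
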