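#' Read a synapse table from CSV
#'
#' Expects a header with columns `pre_id, post_id, pre_site, post_site,
#' count` (missing `count` defaults to 1).
#'
#' @param path CSV file path.
#' @return a [synapse_table()].
#' @export
read_synapse_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pre_id = "character", post_id = "character"))
  need <- c("pre_id", "post_id", "pre_site", "post_site")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!"count" %in% names(d)) d$count <- 1L
  synapse_table(d$pre_id, d$post_id, d$pre_site, d$post_site, d$count)
}

#' Write a connectome to a directory of CSV edge lists
#'
#' Writes one edge-list CSV per connection-type layer
#' (`edges_<type>.csv`: pre_id, post_id, count) plus the node metadata
#' (`nodes.csv`). Node order in all files is the canonical sorted order.
#'
#' @param connectome a `multiplex_connectome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(connectome, dir) {
  stopifnot(inherits(connectome, "multiplex_connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in names(connectome$layers)) {
    A <- connectome$layers[[ty]]
    idx <- Matrix::which(A > 0, arr.ind = TRUE)
    d <- data.frame(pre_id = rownames(A)[idx[, 1]],
                    post_id = colnames(A)[idx[, 2]],
                    count = A[idx])
    d <- d[order(d$pre_id, d$post_id), , drop = FALSE]
    utils::write.csv(d, file.path(dir, paste0("edges_", ty, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(connectome$meta, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param dir directory containing `edges_<type>.csv` files and
#'   `nodes.csv`.
#' @return a `multiplex_connectome`.
#' @export
read_connectome <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE,
                          colClasses = c(node_id = "character"))
  meta <- node_meta(meta$node_id, meta$hemisphere, meta$cell_class,
                    meta$modality, meta$is_input, meta$is_output)
  site_of <- function(ch) ifelse(ch == "a", "axon", "dendrite")
  recs <- list()
  for (ty in LAYER_TYPES) {
    f <- file.path(dir, paste0("edges_", ty, ".csv"))
    if (!file.exists(f)) next
    d <- utils::read.csv(f, stringsAsFactors = FALSE,
                         colClasses = c(pre_id = "character", post_id = "character"))
    if (nrow(d) == 0) next
    recs[[ty]] <- synapse_table(d$pre_id, d$post_id,
                                site_of(substr(ty, 1, 1)),
                                site_of(substr(ty, 2, 2)), d$count)
  }
  build_multiplex(do.call(rbind, recs), meta)
}

#' Export connectome layers as GraphML
#'
#' One GraphML file per layer, with `weight` edge attributes, readable by
#' standard network tools.
#'
#' @param connectome a `multiplex_connectome`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_graphml <- function(connectome, dir) {
  stopifnot(inherits(connectome, "multiplex_connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in names(connectome$layers)) {
    g <- igraph::graph_from_adjacency_matrix(connectome$layers[[ty]],
                                             mode = "directed", weighted = TRUE)
    igraph::write_graph(g, file.path(dir, paste0(ty, ".graphml")),
                        format = "graphml")
  }
  invisible(dir)
}

#' Read a skeleton from SWC-like CSV files
#'
#' The skeleton file needs columns `node_id, parent_id` (plus optional
#' coordinates); the root is the node with parent `-1` (or `NA`). The
#' synapse file has columns `node_id, kind` (`pre`/`post`) and optional
#' `count`.
#'
#' @param swc_path skeleton CSV.
#' @param synapse_path synapse CSV (optional).
#' @return a [skeleton_tree()].
#' @export
read_skeleton_swc <- function(swc_path, synapse_path = NULL) {
  d <- utils::read.csv(swc_path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "parent_id") %in% names(d)))
  pre <- integer(nrow(d)); post <- integer(nrow(d))
  if (!is.null(synapse_path)) {
    syn <- utils::read.csv(synapse_path, stringsAsFactors = FALSE)
    if (!"count" %in% names(syn)) syn$count <- 1L
    i <- match(as.character(syn$node_id), as.character(d$node_id))
    if (anyNA(i)) stop("synapse sites reference unknown skeleton nodes")
    for (k in seq_len(nrow(syn))) {
      if (syn$kind[k] == "pre") pre[i[k]] <- pre[i[k]] + syn$count[k]
      else post[i[k]] <- post[i[k]] + syn$count[k]
    }
  }
  skeleton_tree(d$node_id, d$parent_id, pre, post)
}
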