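#' Create a synapse record table
#'
#' A synapse table holds one row per annotated connection, with the
#' presynaptic and postsynaptic neuron, the compartment (axon or dendrite) on
#' each side, and the number of synaptic contacts it represents.
#'
#' @param pre_id,post_id character vectors of neuron identifiers.
#' @param pre_site,post_site compartment labels, `"axon"` or `"dendrite"`.
#'   `NA` is allowed and routes the record to the unclassified bucket.
#' @param count positive integer synapse counts (default 1).
#' @return a `data.frame` with class `synapse_table`.
#' @export
synapse_table <- function(pre_id, post_id, pre_site, post_site, count = 1L) {
  n <- length(pre_id)
  stopifnot(length(post_id) == n)
  pre_site <- rep_len(as.character(pre_site), n)
  post_site <- rep_len(as.character(post_site), n)
  count <- rep_len(as.integer(count), n)
  ok <- is.na(pre_site) | pre_site %in% c("axon", "dendrite")
  if (!all(ok)) stop("pre_site must be 'axon', 'dendrite' or NA")
  ok <- is.na(post_site) | post_site %in% c("axon", "dendrite")
  if (!all(ok)) stop("post_site must be 'axon', 'dendrite' or NA")
  if (any(count < 1L, na.rm = TRUE)) stop("count must be >= 1")
  out <- data.frame(
    pre_id = as.character(pre_id), post_id = as.character(post_id),
    pre_site = pre_site, post_site = post_site, count = count,
    stringsAsFactors = FALSE
  )
  class(out) <- c("synapse_table", "data.frame")
  out
}

#' Create a node metadata table
#'
#' @param node_id character vector of unique neuron identifiers.
#' @param hemisphere `"left"`, `"right"` or `"center"`.
#' @param cell_class free-form class label (e.g. `"SN"`, `"PN"`, `"DN_VNC"`).
#' @param modality optional sensory modality for input neurons.
#' @param is_input,is_output logical flags.
#' @return a `data.frame` with class `node_meta`.
#' @export
node_meta <- function(node_id, hemisphere = "center", cell_class = "other",
                      modality = NA_character_, is_input = FALSE,
                      is_output = FALSE) {
  n <- length(node_id)
  if (anyDuplicated(node_id)) stop("node_id must be unique")
  hemisphere <- rep_len(as.character(hemisphere), n)
  if (!all(hemisphere %in% c("left", "right", "center")))
    stop("hemisphere must be left, right or center")
  out <- data.frame(
    node_id = as.character(node_id), hemisphere = hemisphere,
    cell_class = rep_len(as.character(cell_class), n),
    modality = rep_len(as.character(modality), n),
    is_input = rep_len(as.logical(is_input), n),
    is_output = rep_len(as.logical(is_output), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("node_meta", "data.frame")
  out
}

#' Classify synapses into the four connection types
#'
#' Maps the (presynaptic, postsynaptic) compartment labels of each record to
#' one of the four connection types: (axon, dendrite) -> `ad`,
#' (axon, axon) -> `aa`, (dendrite, dendrite) -> `dd`,
#' (dendrite, axon) -> `da`. Records with a missing compartment on either
#' side are labelled `"unclassified"`, never dropped.
#'
#' @param records a [synapse_table()].
#' @return the table with an added `type` column.
#' @export
classify_synapses <- function(records) {
  pre <- substr(records$pre_site, 1, 1)
  post <- substr(records$post_site, 1, 1)
  type <- paste0(pre, post)
  type[is.na(records$pre_site) | is.na(records$post_site)] <- "unclassified"
  stopifnot(all(type %in% c(LAYER_TYPES, "unclassified")))
  records$type <- type
  records
}

#' Build a multiplex connectome from a synapse table
#'
#' Aggregates synapse records into four directed, integer-weighted adjacency
#' matrices (one per connection type) over a shared, canonically sorted node
#' set. Self-loops are excluded from all layers and counted; records with
#' missing compartments go to the unclassified bucket.
#'
#' @param records a [synapse_table()].
#' @param meta a [node_meta()] covering every node referenced by `records`.
#' @return an object of class `multiplex_connectome`: a list with `nodes`
#'   (sorted ids), `layers` (named list of `dgCMatrix`), `meta`, and
#'   `excluded` (self-loop and unclassified synapse counts).
#' @export
build_multiplex <- function(records, meta) {
  if (!"type" %in% names(records)) records <- classify_synapses(records)
  ids <- sort(unique(meta$node_id))
  ref <- unique(c(records$pre_id, records$post_id))
  missing <- setdiff(ref, ids)
  if (length(missing) > 0)
    stop("synapse records reference unknown node ids: ",
         paste(utils::head(missing, 10), collapse = ", "))
  n <- length(ids)
  self <- records$pre_id == records$post_id
  unclass <- records$type == "unclassified" & !self
  keep <- !self & !unclass
  layers <- lapply(LAYER_TYPES, function(ty) {
    r <- records[keep & records$type == ty, , drop = FALSE]
    Matrix::sparseMatrix(
      i = match(r$pre_id, ids), j = match(r$post_id, ids), x = r$count,
      dims = c(n, n), dimnames = list(ids, ids)
    )
  })
  names(layers) <- LAYER_TYPES
  meta <- meta[match(ids, meta$node_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(nodes = ids, layers = layers, meta = meta,
         excluded = list(self_loops = sum(records$count[self]),
                         unclassified = sum(records$count[unclass]))),
    class = "multiplex_connectome"
  )
}

#' @export
print.multiplex_connectome <- function(x, ...) {
  cat("multiplex_connectome:", length(x$nodes), "neurons\n")
  for (ty in names(x$layers)) {
    A <- x$layers[[ty]]
    cat(sprintf("  %-3s %6d edges, %8d synapses\n", ty,
                Matrix::nnzero(A), sum(A)))
  }
  cat("  excluded: self-loops =", x$excluded$self_loops,
      ", unclassified =", x$excluded$unclassified, "\n")
  invisible(x)
}

#' Extract one connection-type layer as a sparse adjacency matrix
#'
#' @param x a `multiplex_connectome`.
#' @param type one of `"ad"`, `"aa"`, `"dd"`, `"da"`, or `"sum"` for the
#'   summed graph over all four types.
#' @return a `dgCMatrix` with node ids as dimnames.
#' @export
layer_adjacency <- function(x, type = "ad") {
  stopifnot(inherits(x, "multiplex_connectome"))
  if (identical(type, "sum")) return(Reduce(`+`, x$layers))
  if (!type %in% names(x$layers)) stop("unknown layer: ", type)
  x$layers[[type]]
}

#' Total synapse count held in the connectome layers
#' @param x a `multiplex_connectome`.
#' @return integer total over the four layers.
#' @export
total_synapses <- function(x) {
  sum(vapply(x$layers, function(A) sum(A), numeric(1)))
}

# coerce various graph arguments (connectome, sparse/dense matrix) to a
# base dense matrix with dimnames
as_adjacency <- function(graph, type = "ad") {
  if (inherits(graph, "multiplex_connectome"))
    graph <- layer_adjacency(graph, type)
  if (inherits(graph, "thresholded_graph")) graph <- graph$adjacency
  if (inherits(graph, "Matrix")) graph <- as.matrix(graph)
  if (!is.matrix(graph) || nrow(graph) != ncol(graph))
    stop("graph must be a square adjacency matrix or a connectome")
  if (is.null(rownames(graph))) {
    ids <- as.character(seq_len(nrow(graph)))
    dimnames(graph) <- list(ids, ids)
  }
  graph
}
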