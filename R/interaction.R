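# Merging PPI / TF-target edge lists and extracting subnetworks.
#
# Edge tables are data frames with columns node_a, node_b, optionally
# confidence (0-1 or 0-1000 scale) and source (free-text tag such as "ppi"
# or "tf_target").

new_interaction_network <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

tidy_edge_table <- function(df, default_source) {
  if (!all(c("node_a", "node_b") %in% names(df))) {
    stop("edge table needs columns node_a and node_b", call. = FALSE)
  }
  out <- data.frame(
    node_a = canonicalize_symbols(df$node_a),
    node_b = canonicalize_symbols(df$node_b),
    confidence = if ("confidence" %in% names(df))
      suppressWarnings(as.numeric(df$confidence)) else NA_real_,
    source = if ("source" %in% names(df))
      as.character(df$source) else default_source,
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(out$node_a) | !nzchar(out$node_b) |
    is.na(df$node_a) | is.na(df$node_b)
  if ("confidence" %in% names(df)) {
    # a confidence that fails to parse as a number is malformed; a missing
    # one is allowed (passes the filter)
    bad <- bad | (is.na(out$confidence) & !is.na(df$confidence))
  }
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed edge row(s)", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  # published confidences are often on a 0-1000 scale; rescale before
  # thresholding
  if (any(!is.na(out$confidence)) &&
      max(out$confidence, na.rm = TRUE) > 1) {
    out$confidence <- out$confidence / 1000
  }
  out
}

#' Merge interaction edge lists into one undirected network
#'
#' Edges are canonicalized (undirected, `node_a < node_b`, self-loops
#' dropped) and filtered to confidence strictly greater than
#' `min_confidence`; rows without a confidence score pass unfiltered.
#' Confidences on a 0-1000 scale are detected (maximum > 1) and divided by
#' 1000 before thresholding. Duplicate edges are collapsed keeping the
#' maximum confidence and the union of source tags.
#'
#' @param edge_lists a list of edge-table data frames (columns `node_a`,
#'   `node_b`, optional `confidence`, `source`).
#' @param min_confidence strict lower confidence bound (default 0.85).
#' @return an `interaction_network` object.
#' @export
merge_networks <- function(edge_lists, min_confidence = 0.85) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  if (length(edge_lists) == 0L) stop("no edge lists given", call. = FALSE)
  check_scalar_number(min_confidence, "min_confidence")
  parts <- lapply(seq_along(edge_lists), function(i) {
    tidy_edge_table(edge_lists[[i]], default_source = sprintf("list%d", i))
  })
  e <- do.call(rbind, parts)
  if (nrow(e) == 0L) stop("all edge rows were malformed", call. = FALSE)
  keep <- is.na(e$confidence) | e$confidence > min_confidence
  e <- e[keep & e$node_a != e$node_b, , drop = FALSE]
  if (nrow(e) == 0L) {
    warning("no edges survive the confidence filter", call. = FALSE)
    return(new_interaction_network(e))
  }
  flip <- e$node_a > e$node_b
  tmp <- e$node_a[flip]; e$node_a[flip] <- e$node_b[flip]
  e$node_b[flip] <- tmp
  key <- paste(e$node_a, e$node_b, sep = "\r")
  merged <- do.call(rbind, lapply(split(e, key), function(grp) {
    data.frame(
      node_a = grp$node_a[1L], node_b = grp$node_b[1L],
      confidence = if (all(is.na(grp$confidence))) NA_real_
        else max(grp$confidence, na.rm = TRUE),
      source = paste(sort(unique(unlist(strsplit(grp$source, ",")))),
                     collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  merged <- merged[order(merged$node_a, merged$node_b), , drop = FALSE]
  rownames(merged) <- NULL
  new_interaction_network(merged)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Subnetwork induced by a gene set
#'
#' Keeps the nodes present in both the network and the gene set, and the
#' edges with both endpoints inside.
#'
#' @param net an `interaction_network`.
#' @param gene_set character vector of gene symbols.
#' @return an `interaction_network`; empty (with a warning) if no node of
#'   the set is in the network.
#' @export
induced_subnetwork <- function(net, gene_set) {
  stopifnot(inherits(net, "interaction_network"))
  keep_nodes <- intersect(net$nodes, canonicalize_symbols(gene_set))
  e <- net$edges
  e <- e[e$node_a %in% keep_nodes & e$node_b %in% keep_nodes, , drop = FALSE]
  if (length(keep_nodes) == 0L) {
    warning("gene set shares no nodes with the network", call. = FALSE)
  }
  out <- new_interaction_network(e)
  out$nodes <- sort(keep_nodes)  # keep isolated nodes of the set
  out
}

#' Ego subnetwork around a seed gene
#'
#' The seed plus every node within graph distance `radius`, and all edges
#' among them (the closed neighborhood for `radius = 1`). TF-target edges
#' are treated as undirected, so the neighborhood mixes upstream and
#' downstream interactors.
#'
#' @param net an `interaction_network`.
#' @param seed_gene gene symbol; must be a node of the network.
#' @param radius neighborhood radius (default 1; 0 gives the seed alone).
#' @return an `interaction_network`.
#' @export
ego_subnetwork <- function(net, seed_gene, radius = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  seed_gene <- canonicalize_symbols(seed_gene)
  radius <- check_count(radius, "radius", min = 0L)
  if (!seed_gene %in% net$nodes) {
    stop("seed gene '", seed_gene, "' is not in the network", call. = FALSE)
  }
  g <- as_igraph(net)
  nbhd <- igraph::ego(g, order = radius, nodes = seed_gene)[[1L]]
  induced_subnetwork(net, names(nbhd))
}

#' Read an interaction edge table from TSV
#'
#' Expected columns: `node_a`, `node_b`, optional `confidence`, `source`.
#'
#' @param path file path.
#' @param sep delimiter (default tab).
#' @return data frame suitable for [merge_networks()].
#' @export
read_edge_list <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an interaction network as TSV (and optionally GraphML)
#'
#' @param net an `interaction_network`.
#' @param tsv_path,graphml_path output paths (`NULL` to skip either).
#' @return invisible list of paths written.
#' @export
write_interaction_network <- function(net, tsv_path = NULL,
                                      graphml_path = NULL) {
  written <- list()
  if (!is.null(tsv_path)) {
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$tsv <- tsv_path
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  invisible(written)
}
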