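# Differential network construction, topological-overlap module detection
# and signed-connectivity hub scoring.

#' Scale a symmetric delta matrix to a [0, 1] adjacency
#'
#' `A_ij = |delta_ij| / max_kl |delta_kl|` (the zero matrix when the
#' maximum is 0), with the diagonal forced to 0. This is the adjacency on
#' which the topological overlap is computed.
#'
#' @param delta_mat symmetric finite numeric matrix of delta values.
#' @return symmetric adjacency matrix with entries in `[0, 1]` and zero
#'   diagonal.
#' @export
scale_delta_matrix <- function(delta_mat) {
  check_symmetric(delta_mat, "delta_mat")
  a <- abs(delta_mat)
  diag(a) <- 0
  mx <- max(a)
  if (mx > 0) a <- a / mx
  a
}

#' Topological overlap matrix of a weighted adjacency
#'
#' For an adjacency `A` in `[0, 1]` with zero diagonal,
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for
#' `i != j`, where `k_i = sum_u A_iu` is the weighted connectivity, and
#' `TOM_ii = 1`. Shared neighbours raise the overlap of a pair beyond its
#' direct adjacency, which makes the subsequent clustering robust to
#' individual noisy edges.
#'
#' @param A symmetric adjacency, entries in `[0, 1]`, zero diagonal.
#' @return symmetric TOM matrix with entries in `[0, 1]` and unit diagonal.
#' @export
topological_overlap <- function(A) {
  check_symmetric(A, "A")
  if (any(A < 0) || any(A > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(diag(A) != 0)) stop("adjacency diagonal must be 0", call. = FALSE)
  k <- rowSums(A)
  shared <- A %*% A          # sum_u A_iu * A_uj (diagonal of A is 0)
  num <- shared + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # symmetrize away float asymmetry
  tom
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`. The default
#' `"dynamic"` cut slices the dendrogram at the 0.99 quantile of merge
#' heights (a hybrid-style branch cut); clusters smaller than
#' `min_module_size` are unassigned (label 0). `method = "fixed_k"` cuts
#' into exactly `k` clusters instead. Genes with no TOM connectivity at all
#' (zero overlap with every other gene) are unassigned before clustering.
#' Modules are relabelled 1, 2, ... by decreasing size, ties broken by the
#' lowest member gene index, so the labelling is deterministic.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size smallest cluster kept as a module (default 20).
#' @param method `"dynamic"` (quantile cut) or `"fixed_k"`.
#' @param k number of clusters for `method = "fixed_k"`.
#' @param cut_quantile quantile of merge heights used by the dynamic cut
#'   (default 0.99).
#' @return data frame with columns `gene` and `module` (0 = unassigned),
#'   one row per gene in TOM order; the `hclust` tree in attribute `"tree"`.
#' @export
detect_modules <- function(tom, min_module_size = 20L,
                           method = c("dynamic", "fixed_k"), k = NULL,
                           cut_quantile = 0.99) {
  method <- match.arg(method)
  check_symmetric(tom, "tom")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- default_gene_names(nrow(tom))
  n <- nrow(tom)
  min_module_size <- check_count(min_module_size, "min_module_size")

  connectivity <- rowSums(tom) - diag(tom)
  connected <- connectivity > 0
  labels <- integer(n)
  tree <- NULL

  if (sum(connected) < 3L) {
    if (sum(connected) > 0L) {
      warning("fewer than 3 connected genes; assigning them one module",
              call. = FALSE)
      labels[connected] <- 1L
    }
  } else {
    sub <- tom[connected, connected, drop = FALSE]
    d <- stats::as.dist(1 - sub)
    tree <- stats::hclust(d, method = "average")
    cl <- if (method == "fixed_k") {
      k <- check_count(k, "k")
      stats::cutree(tree, k = k)
    } else {
      h <- stats::quantile(tree$height, cut_quantile, names = FALSE)
      stats::cutree(tree, h = h)
    }
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= min_module_size])
    lab_sub <- ifelse(cl %in% keep, cl, 0L)
    labels[connected] <- lab_sub
  }

  labels <- relabel_by_size(labels)
  out <- data.frame(gene = genes, module = labels, stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

# Renumber nonzero labels by decreasing size; ties by lowest member index.
relabel_by_size <- function(labels) {
  nz <- setdiff(unique(labels), 0L)
  if (length(nz) == 0L) return(labels)
  size <- vapply(nz, function(l) sum(labels == l), integer(1))
  first <- vapply(nz, function(l) which(labels == l)[1L], integer(1))
  ord <- nz[order(-size, first)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  new
}

# Signed scaled-delta edge weights in [-1, 1]; shared by connectivity and
# the exports.
edge_weights <- function(edges, weight_mode = c("scaled_delta", "r_diff")) {
  weight_mode <- match.arg(weight_mode)
  if (weight_mode == "scaled_delta") {
    mx <- max(abs(edges$delta))
    if (mx == 0) rep(0, nrow(edges)) else edges$delta / mx
  } else {
    pmax(-1, pmin(1, edges$r_R - edges$r_S))
  }
}

#' Signed intramodular connectivity (kWithin)
#'
#' For each gene u in module M, `kWithin(u) = conn+(u) - conn-(u)` over the
#' *significant intramodular* edges at u, where `conn+` is the sum of the
#' positive edge weights and `conn-` the absolute sum of the negative ones.
#' Edge weights lie in `[-1, 1]`: by default the signed scaled delta,
#' `sign(delta) * |delta| / max|delta|`; alternatively the clipped raw
#' correlation difference `r_R - r_S`. High kWithin marks module hubs whose
#' correlations are systematically higher in condition R.
#'
#' @param edges a `diffcorr_edges` data frame (all pairs; only rows with
#'   `significant == TRUE` contribute).
#' @param assignment module assignment data frame (`gene`, `module`) from
#'   [detect_modules()]; every edge endpoint must appear in it.
#' @param weight_mode `"scaled_delta"` (default) or `"r_diff"`.
#' @return the assignment data frame with columns `kWithin`, `conn_pos`,
#'   `conn_neg` and `n_intramodular_edges` added (zero for unassigned
#'   genes).
#' @export
signed_connectivity <- function(edges, assignment,
                                weight_mode = c("scaled_delta", "r_diff")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(assignment),
            all(c("gene", "module") %in% names(assignment)))
  lab <- assignment$module
  names(lab) <- assignment$gene
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), names(lab))
  if (length(missing) > 0L) {
    stop("edge endpoint(s) missing from the module assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  w_all <- edge_weights(edges, weight_mode)
  sig <- edges$significant
  la <- lab[edges$gene_a]
  lb <- lab[edges$gene_b]
  intra <- sig & la == lb & la > 0L

  conn_pos <- conn_neg <- n_edges <- stats::setNames(
    numeric(nrow(assignment)), assignment$gene)
  if (any(intra)) {
    w <- w_all[intra]
    ends <- c(edges$gene_a[intra], edges$gene_b[intra])
    ww <- c(w, w)
    pos <- tapply(pmax(ww, 0), ends, sum)
    neg <- tapply(pmax(-ww, 0), ends, sum)
    cnt <- tapply(ww, ends, length)
    conn_pos[names(pos)] <- pos
    conn_neg[names(neg)] <- neg
    n_edges[names(cnt)] <- cnt
  }
  assignment$kWithin <- unname(conn_pos - conn_neg)
  assignment$conn_pos <- unname(conn_pos)
  assignment$conn_neg <- unname(conn_neg)
  assignment$n_intramodular_edges <- as.integer(unname(n_edges))
  assignment
}

#' Build the differential network object
#'
#' Collects the significant edges, the node set (genes carrying at least
#' one significant edge) and the full scaled-|delta| adjacency over all
#' analyzed genes.
#'
#' @param edges a `diffcorr_edges` data frame.
#' @return object of class `differential_network`: list with `nodes`,
#'   `edges` (significant rows only), `adjacency` and `genes` (all analyzed
#'   genes).
#' @export
differential_network <- function(edges) {
  adj <- scale_delta_matrix(delta_matrix(edges))
  sig <- edges[edges$significant, , drop = FALSE]
  nodes <- sort(unique(c(sig$gene_a, sig$gene_b)))
  structure(list(nodes = nodes, edges = sig, adjacency = adj,
                 genes = rownames(adj)),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("Differential network: %d nodes, %d significant edges (of %d genes analyzed)\n",
              length(x$nodes), nrow(x$edges), length(x$genes)))
  invisible(x)
}

#' Largest connected component of a module's significant-edge subgraph
#'
#' @param network a `differential_network`.
#' @param assignment module assignment data frame (`gene`, `module`).
#' @param module_label module to inspect (positive integer).
#' @return character vector of node names in the largest component, sorted;
#'   empty (with a warning) when the module has no significant edges. Ties
#'   in component size are broken by the smallest lexicographic node name.
#' @export
largest_component <- function(network, assignment, module_label) {
  stopifnot(inherits(network, "differential_network"))
  module_label <- check_count(module_label, "module_label")
  members <- assignment$gene[assignment$module == module_label]
  if (length(members) == 0L) {
    stop("module ", module_label, " does not exist", call. = FALSE)
  }
  e <- network$edges
  e <- e[e$gene_a %in% members & e$gene_b %in% members, , drop = FALSE]
  if (nrow(e) == 0L) {
    warning("module ", module_label, " has no significant edges",
            call. = FALSE)
    return(character(0))
  }
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  comp_nodes <- split(igraph::V(g)$name, comp$membership)
  sizes <- lengths(comp_nodes)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(comp_nodes[best], function(v) min(v), character(1))
    best <- best[order(mins)][1L]
  }
  sort(comp_nodes[[best]])
}

#' Top hub genes by signed connectivity
#'
#' @param kwithin named numeric vector of kWithin values, or the data frame
#'   from [signed_connectivity()] (optionally restricted with `module`).
#' @param top_n number of hubs to return.
#' @param module optional module label to restrict to (data-frame input).
#' @return character vector of gene names sorted by decreasing kWithin,
#'   ties broken by name.
#' @export
hub_nodes <- function(kwithin, top_n, module = NULL) {
  top_n <- check_count(top_n, "top_n")
  if (is.data.frame(kwithin)) {
    df <- kwithin
    if (!is.null(module)) df <- df[df$module == module, , drop = FALSE]
    kwithin <- stats::setNames(df$kWithin, df$gene)
  }
  ord <- order(-kwithin, names(kwithin))
  utils::head(names(kwithin)[ord], top_n)
}

#' Export a differential network for Cytoscape and GraphML consumers
#'
#' Writes the significant edges as a Cytoscape-compatible TSV
#' (`source`, `target`, `weight`, `sign`, `lfdr`) and, optionally, as
#' GraphML with module and kWithin node attributes.
#'
#' @param network a `differential_network`.
#' @param assignment module assignment with kWithin (from
#'   [signed_connectivity()]); optional for the TSV.
#' @param tsv_path,graphml_path output paths (`NULL` to skip either).
#' @param weight_mode edge weight mode passed to the exporter.
#' @return invisible list of the paths written.
#' @export
export_network <- function(network, assignment = NULL, tsv_path = NULL,
                           graphml_path = NULL,
                           weight_mode = c("scaled_delta", "r_diff")) {
  weight_mode <- match.arg(weight_mode)
  e <- network$edges
  w <- if (nrow(e)) edge_weights(e, weight_mode) else numeric(0)
  written <- list()
  if (!is.null(tsv_path)) {
    out <- data.frame(source = e$gene_a, target = e$gene_b,
                      weight = format_num(w), sign = as.integer(e$sign),
                      lfdr = format_num(e$lfdr), stringsAsFactors = FALSE)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$tsv <- tsv_path
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$gene_a, to = e$gene_b, weight = w,
                 sign = as.integer(e$sign), lfdr = e$lfdr),
      directed = FALSE,
      vertices = data.frame(name = network$nodes))
    if (!is.null(assignment)) {
      m <- match(network$nodes, assignment$gene)
      igraph::V(g)$module <- assignment$module[m]
      if ("kWithin" %in% names(assignment)) {
        igraph::V(g)$kWithin <- assignment$kWithin[m]
      }
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  invisible(written)
}

#' Write a module assignment table as TSV
#'
#' Columns: gene, module, kWithin, n_intramodular_edges.
#'
#' @param assignment data frame from [signed_connectivity()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(assignment, path) {
  out <- data.frame(gene = assignment$gene, module = assignment$module,
                    kWithin = format_num(assignment$kWithin),
                    n_intramodular_edges = assignment$n_intramodular_edges,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
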