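# Configuration-driven end-to-end pipeline:
# intersect -> correlate -> delta/lfdr -> network -> modules -> kWithin ->
# exports + JSON manifest.

#' Build a pipeline configuration
#'
#' Exactly one of a file-input pair (`expr_R` + `expr_S` paths) or an
#' inline synthetic spec must be given.
#'
#' @param expr_R,expr_S paths to gene-by-sample expression TSV/CSV files
#'   (normalized, e.g. variance-stabilized, values).
#' @param synthetic a [synthetic_spec()] object, generated instead of file
#'   input.
#' @param markers optional path to a marker list (one symbol per line) or a
#'   character vector of symbols; `NULL` analyzes all shared genes.
#' @param out_dir output directory (created if needed).
#' @param lfdr_threshold edge significance cutoff (default 0.05).
#' @param min_module_size smallest reported module (default 20).
#' @param cut_method `"dynamic"` or `"fixed_k"`; `k` for the latter.
#' @param k fixed number of clusters when `cut_method = "fixed_k"`.
#' @param weight_mode kWithin edge weights: `"scaled_delta"` or `"r_diff"`.
#' @param lfdr_input `"delta"` or `"pvalue"`.
#' @param cluster_all_genes cluster all analyzed genes (default `TRUE`) or
#'   only those carrying a significant edge.
#' @param seed integer seed driving any randomness (synthetic generation).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expr_R = NULL, expr_S = NULL, synthetic = NULL,
                            markers = NULL, out_dir = "diffcornet_out",
                            lfdr_threshold = 0.05, min_module_size = 20L,
                            cut_method = c("dynamic", "fixed_k"), k = NULL,
                            weight_mode = c("scaled_delta", "r_diff"),
                            lfdr_input = c("delta", "pvalue"),
                            cluster_all_genes = TRUE, seed = 1L) {
  cut_method <- match.arg(cut_method)
  weight_mode <- match.arg(weight_mode)
  lfdr_input <- match.arg(lfdr_input)
  file_input <- !is.null(expr_R) || !is.null(expr_S)
  if (file_input && is.null(synthetic)) {
    if (is.null(expr_R) || is.null(expr_S)) {
      stop("both `expr_R` and `expr_S` paths are required for file input",
           call. = FALSE)
    }
  } else if (!file_input && !is.null(synthetic)) {
    if (!inherits(synthetic, "synthetic_spec")) {
      stop("`synthetic` must be a synthetic_spec object", call. = FALSE)
    }
  } else {
    stop("give exactly one of {expr_R + expr_S file paths} or ",
         "{a synthetic spec}", call. = FALSE)
  }
  check_scalar_number(lfdr_threshold, "lfdr_threshold", positive = TRUE)
  if (lfdr_threshold > 1) stop("`lfdr_threshold` must be <= 1", call. = FALSE)
  structure(list(expr_R = expr_R, expr_S = expr_S, synthetic = synthetic,
                 markers = markers, out_dir = out_dir,
                 lfdr_threshold = lfdr_threshold,
                 min_module_size = check_count(min_module_size,
                                               "min_module_size"),
                 cut_method = cut_method, k = k,
                 weight_mode = weight_mode, lfdr_input = lfdr_input,
                 cluster_all_genes = isTRUE(cluster_all_genes),
                 seed = check_count(seed, "seed",
                                    min = -.Machine$integer.max)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` mapping is passed to [synthetic_spec()].
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file's.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_spec, y$synthetic)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- config$seed  # one seed field drives all randomness
    sim <- generate_expression_pair(spec)
    list(expr_R = sim$expr_R, expr_S = sim$expr_S, truth = sim$truth,
         input_desc = "synthetic")
  } else {
    list(expr_R = read_matrix_tsv(config$expr_R),
         expr_S = read_matrix_tsv(config$expr_S),
         truth = NULL,
         input_desc = c(config$expr_R, config$expr_S))
  }
}

#' Run the differential co-expression pipeline
#'
#' Executes marker intersection, per-condition correlation, the
#' Fisher-z difference statistics with local-FDR edge selection, network
#' construction, TOM module detection and signed-connectivity scoring, and
#' writes the edge table, module table, Cytoscape edge TSV, GraphML and a
#' JSON run manifest into `config$out_dir`. Any stage failure aborts with
#' the stage name and removes partial outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML config file).
#' @return the manifest, invisibly, as a named list (also written as
#'   `manifest.json`).
#' @export
run_differential_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- file.path(out_dir, c("edges.tsv", "modules.tsv",
                                    "network_cytoscape.tsv",
                                    "network.graphml", "manifest.json"))
  names(out_files) <- c("edges", "modules", "cytoscape", "graphml",
                        "manifest")
  stage <- "setup"
  cleanup <- function() {
    suppressWarnings(file.remove(out_files[file.exists(out_files)]))
    if (created) unlink(out_dir, recursive = TRUE)
  }
  tryCatch({
    stage <- "input"
    inp <- pipeline_inputs(config)

    stage <- "intersect"
    if (!is.null(config$markers)) {
      markers <- if (length(config$markers) == 1L &&
                     file.exists(config$markers)) {
        read_marker_list(config$markers)
      } else {
        config$markers
      }
      ix <- intersect_markers(inp$expr_R, inp$expr_S, markers)
    } else {
      ix <- intersect_markers(inp$expr_R, inp$expr_S,
                              rownames(inp$expr_R))
    }

    stage <- "correlate"
    set_R <- correlation_matrix(ix$expr_R, condition = "R")
    set_S <- correlation_matrix(ix$expr_S, condition = "S")

    stage <- "delta/lfdr"
    edges <- build_edge_table(set_R, set_S,
                              lfdr_threshold = config$lfdr_threshold,
                              lfdr_input = config$lfdr_input)

    stage <- "network"
    net <- differential_network(edges)

    stage <- "modules"
    adj <- net$adjacency
    if (!config$cluster_all_genes) {
      keep <- rownames(adj) %in% net$nodes
      adj <- adj[keep, keep, drop = FALSE]
    }
    tom <- topological_overlap(adj)
    assignment <- detect_modules(tom,
                                 min_module_size = config$min_module_size,
                                 method = config$cut_method, k = config$k)
    if (!config$cluster_all_genes) {
      # genes excluded from clustering stay unassigned
      rest <- setdiff(net$genes, assignment$gene)
      if (length(rest)) {
        assignment <- rbind(assignment,
                            data.frame(gene = rest, module = 0L,
                                       stringsAsFactors = FALSE))
      }
    }

    stage <- "kWithin"
    assignment <- signed_connectivity(edges, assignment,
                                      weight_mode = config$weight_mode)
    # a module of the differential network must carry differential signal:
    # clusters with no significant intramodular edge are unassigned
    empty <- vapply(setdiff(unique(assignment$module), 0L), function(m) {
      sum(assignment$n_intramodular_edges[assignment$module == m]) == 0L
    }, logical(1))
    drop_mods <- setdiff(unique(assignment$module), 0L)[empty]
    if (length(drop_mods)) {
      assignment$module[assignment$module %in% drop_mods] <- 0L
      assignment$module <- relabel_by_size(assignment$module)
    }

    stage <- "export"
    write_edge_table(edges, out_files[["edges"]])
    write_module_table(assignment, out_files[["modules"]])
    export_network(net, assignment, tsv_path = out_files[["cytoscape"]],
                   graphml_path = out_files[["graphml"]],
                   weight_mode = config$weight_mode)

    stage <- "manifest"
    module_sizes <- table(assignment$module[assignment$module > 0])
    manifest <- list(
      package = "diffcornet",
      version = as.character(utils::packageVersion("diffcornet")),
      input = inp$input_desc,
      output_md5 = as.list(vapply(out_files[c("edges", "modules")],
                                  file_sha, character(1))),
      parameters = list(
        lfdr_threshold = config$lfdr_threshold,
        min_module_size = config$min_module_size,
        cut_method = config$cut_method, k = config$k,
        weight_mode = config$weight_mode,
        lfdr_input = config$lfdr_input,
        cluster_all_genes = config$cluster_all_genes,
        seed = config$seed
      ),
      n_genes_analyzed = length(net$genes),
      n_pairs_evaluated = nrow(edges),
      n_nodes = length(net$nodes),
      n_significant_edges = nrow(net$edges),
      n_modules = length(module_sizes),
      module_sizes = as.list(stats::setNames(as.integer(module_sizes),
                                             names(module_sizes))),
      eta0 = attr(edges, "eta0"),
      null_scale = attr(edges, "null_scale")
    )
    jsonlite::write_json(manifest, out_files[["manifest"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    cleanup()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

file_sha <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  # plain content hash; tools::md5sum ships with base R
  unname(tools::md5sum(path))
}
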