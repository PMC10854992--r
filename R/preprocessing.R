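# Count filtering, marker intersection and a convenience normalization.

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("count matrix must be a non-empty matrix", call. = FALSE)
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop("count matrix must have gene rownames", call. = FALSE)
  }
  invisible(counts)
}

#' Filter genes by minimum count prevalence
#'
#' Retains a gene iff it has at least `min_count` counts in at least
#' `min_fraction` of the samples. With the defaults this is the rule
#' "at least 1 count in at least half the samples"; "at least half" is a
#' non-strict comparison, so a gene present in exactly half the samples is
#' retained. Gene order and the sample set are unchanged.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param min_count minimum per-sample count (default 1).
#' @param min_fraction minimum fraction of qualifying samples, in `(0, 1]`
#'   (default 0.5).
#' @return the filtered count matrix.
#' @export
#' @examples
#' m <- rbind(keep = c(1L, 0L, 2L, 0L), drop = c(0L, 0L, 0L, 5L))
#' colnames(m) <- paste0("s", 1:4)
#' rownames(filter_low_counts(m))
filter_low_counts <- function(counts, min_count = 1L, min_fraction = 0.5) {
  check_count_matrix(counts)
  check_scalar_number(min_fraction, "min_fraction")
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  }
  min_count <- check_count(min_count, "min_count", min = 0L)
  keep <- rowSums(counts >= min_count) >= min_fraction * ncol(counts)
  counts[keep, , drop = FALSE]
}

#' Restrict two expression matrices to a shared marker list
#'
#' Subsets both condition matrices to the markers present in *both*, in
#' marker-list order, after canonicalizing symbols (uppercase, trimmed).
#' Genes that are constant (zero variance) in either condition cannot enter
#' a correlation analysis and are dropped here with a warning.
#'
#' @param expr_R,expr_S gene-by-sample numeric matrices for the two
#'   conditions.
#' @param markers character vector of marker symbols (e.g. from
#'   [read_marker_list()]).
#' @return a list with `expr_R`, `expr_S` (aligned sub-matrices) and
#'   `report`, a list recording markers missing from R, from S, or both,
#'   zero-variance drops and the final analyzable count.
#' @export
intersect_markers <- function(expr_R, expr_S, markers) {
  for (nm in c("expr_R", "expr_S")) {
    m <- get(nm)
    if (!is.matrix(m) || is.null(rownames(m))) {
      stop(sprintf("`%s` must be a matrix with gene rownames", nm),
           call. = FALSE)
    }
    if (anyDuplicated(canonicalize_symbols(rownames(m)))) {
      stop(sprintf("`%s` has duplicate gene identifiers after canonicalization",
                   nm), call. = FALSE)
    }
  }
  markers <- unique(canonicalize_symbols(markers))
  rn_R <- canonicalize_symbols(rownames(expr_R))
  rn_S <- canonicalize_symbols(rownames(expr_S))
  in_R <- markers %in% rn_R
  in_S <- markers %in% rn_S
  common <- markers[in_R & in_S]
  report <- list(
    n_markers = length(markers),
    missing_R = markers[!in_R & in_S],
    missing_S = markers[in_R & !in_S],
    missing_both = markers[!in_R & !in_S],
    dropped_zero_variance = character(0)
  )
  if (length(common) == 0L) {
    stop("no analyzable markers: the marker list shares no genes with both ",
         "matrices", call. = FALSE)
  }
  sub_R <- expr_R[match(common, rn_R), , drop = FALSE]
  sub_S <- expr_S[match(common, rn_S), , drop = FALSE]
  rownames(sub_R) <- rownames(sub_S) <- common
  zero_var <- apply(sub_R, 1, stats::var) == 0 |
    apply(sub_S, 1, stats::var) == 0
  if (any(zero_var)) {
    report$dropped_zero_variance <- common[zero_var]
    warning("dropping ", sum(zero_var),
            " zero-variance gene(s): ",
            paste(utils::head(common[zero_var], 5), collapse = ", "),
            call. = FALSE)
    sub_R <- sub_R[!zero_var, , drop = FALSE]
    sub_S <- sub_S[!zero_var, , drop = FALSE]
  }
  if (nrow(sub_R) == 0L) {
    stop("no analyzable markers: all common genes have zero variance",
         call. = FALSE)
  }
  report$n_common <- nrow(sub_R)
  list(expr_R = sub_R, expr_S = sub_S, report = report)
}

#' Median-of-ratios log normalization of a count matrix
#'
#' A convenience normalization for when variance-stabilized expression is
#' not supplied: per-sample size factors are the median ratio of counts to
#' the gene-wise geometric mean, computed over genes with no zero counts,
#' and values are `log2(count / sizeFactor + pseudocount)`. If no gene is
#' zero-free the size factors fall back to total-count scaling (column sums
#' over their geometric mean) with a warning.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudocount added before the log (default 1).
#' @return numeric matrix of normalized log2 expression, with the size
#'   factors in attribute `"size_factors"`.
#' @export
log_normalize <- function(counts, pseudocount = 1) {
  check_count_matrix(counts)
  check_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  ref <- rowSums(counts == 0) == 0L
  if (any(ref)) {
    log_geo <- rowMeans(log(counts[ref, , drop = FALSE]))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
      exp(stats::median(log(col) - log_geo))
    })
  } else {
    warning("no zero-free reference genes; falling back to total-count ",
            "size factors", call. = FALSE)
    tot <- colSums(counts)
    if (any(tot == 0)) {
      stop("cannot normalize: some samples have zero total counts",
           call. = FALSE)
    }
    sf <- tot / exp(mean(log(tot)))
  }
  norm <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  attr(norm, "size_factors") <- sf
  norm
}
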