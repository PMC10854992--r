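# Per-condition correlation, Fisher z, the standardized difference
# statistic, and the differential edge table.

#' Per-condition correlation set
#'
#' Computes the Pearson correlation matrix of a condition's expression
#' (genes correlated across samples) together with its Fisher z transform.
#'
#' @param expr gene-by-sample numeric matrix; `>= 2` samples, no
#'   zero-variance genes (drop them with [intersect_markers()] first).
#' @param condition condition tag, e.g. `"R"` or `"S"`.
#' @return an object of class `correlation_set`: list with `r` (correlation
#'   matrix, unit diagonal), `z` (Fisher transform, zero diagonal by
#'   convention since `z(1)` is infinite), `n` (sample count), `genes` and
#'   `condition`.
#' @export
correlation_matrix <- function(expr, condition = "R") {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(rownames(expr))) {
    stop("`expr` must be a numeric matrix with gene rownames", call. = FALSE)
  }
  if (ncol(expr) < 2L) stop("need >= 2 samples to correlate", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s) reached correlation_matrix(): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "),
         "; drop them upstream", call. = FALSE)
  }
  r <- stats::cor(t(expr))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  z <- r
  diag(z) <- 0  # z(1) is infinite; the diagonal is never used downstream
  z[] <- fisher_z(as.vector(z))
  structure(list(r = r, z = z, n = ncol(expr), genes = rownames(expr),
                 condition = condition),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("Correlation set '%s': %d genes over %d samples\n",
              x$condition, length(x$genes), x$n))
  invisible(x)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing transform
#' under which correlation differences are approximately normal. Values at
#' or beyond +/-1 (duplicate genes, numerical overshoot) are clipped to
#' magnitude `1 - 1e-15` with a warning rather than producing infinities.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of z values; an odd function of `r`.
#' @export
#' @examples
#' fisher_z(c(0, 0.9, -0.9))
fisher_z <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("`r` must be finite numeric", call. = FALSE)
  }
  clip <- abs(r) >= 1
  if (any(clip)) {
    warning(sum(clip), " correlation(s) with |r| >= 1 clipped before the ",
            "Fisher transform", call. = FALSE)
    r[clip] <- sign(r[clip]) * (1 - 1e-15)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Standardized difference of Fisher-transformed correlations
#'
#' `delta = (z_R - z_S) / sqrt(1/(n_R - 3) + 1/(n_S - 3))`: the two-sample
#' z-difference statistic, approximately standard normal for a null gene
#' pair. Antisymmetric under swapping the conditions.
#'
#' @param z_R,z_S Fisher z values (vectors of equal length).
#' @param n_R,n_S per-condition sample counts; both must exceed 3 because
#'   the variance term `1/(n - 3)` is undefined otherwise.
#' @return numeric vector of delta values.
#' @export
#' @examples
#' delta_statistic(0.816497, 0, 6, 6)  # denominator sqrt(2/3)
delta_statistic <- function(z_R, z_S, n_R, n_S) {
  n_R <- check_count(n_R, "n_R")
  n_S <- check_count(n_S, "n_S")
  if (n_R <= 3L || n_S <= 3L) {
    stop("sample counts must be > 3: the statistic's denominator is ",
         "sqrt(1/(n_R - 3) + 1/(n_S - 3))", call. = FALSE)
  }
  if (any(!is.finite(z_R)) || any(!is.finite(z_S))) {
    stop("z values must be finite", call. = FALSE)
  }
  (z_R - z_S) / sqrt(1 / (n_R - 3) + 1 / (n_S - 3))
}

#' Two-sided normal p-value for a delta statistic
#'
#' `p = 2 * (1 - pnorm(|delta|))`, the two-sided tail probability under the
#' standard normal reference.
#'
#' @param delta numeric vector of finite delta values.
#' @return p-values in `(0, 1]`.
#' @export
edge_pvalue <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta))) {
    stop("`delta` must be finite numeric", call. = FALSE)
  }
  2 * stats::pnorm(-abs(delta))
}

#' Differential edge table for all gene pairs
#'
#' Evaluates every unordered gene pair: per-condition correlations and
#' Fisher z values, the standardized difference `delta`, its two-sided
#' normal p-value, and a local false discovery rate computed jointly over
#' all pairs (see [local_fdr()]). An edge is `significant` when
#' `lfdr < lfdr_threshold` (strict). `sign` is `+1` where the correlation is
#' higher in condition R, `-1` where higher in S.
#'
#' @param set_R,set_S `correlation_set` objects for the two conditions with
#'   identical gene sets in identical order.
#' @param lfdr_threshold significance cutoff on the lfdr (default 0.05).
#' @param lfdr_input `"delta"` (default) feeds the statistics to the
#'   empirical-null lfdr; `"pvalue"` feeds the two-sided p-values with a
#'   uniform null instead.
#' @return data frame of class `diffcorr_edges` with columns `gene_a`,
#'   `gene_b` (lexicographic, `gene_a < gene_b`), `r_R`, `r_S`, `z_R`,
#'   `z_S`, `delta`, `p_value`, `lfdr`, `significant`, `sign`; attributes
#'   `n_R`, `n_S`, `eta0` (estimated null proportion) and `lfdr_threshold`.
#' @export
build_edge_table <- function(set_R, set_S, lfdr_threshold = 0.05,
                             lfdr_input = c("delta", "pvalue")) {
  lfdr_input <- match.arg(lfdr_input)
  if (!inherits(set_R, "correlation_set") ||
      !inherits(set_S, "correlation_set")) {
    stop("inputs must be correlation_set objects", call. = FALSE)
  }
  if (!identical(set_R$genes, set_S$genes)) {
    only_R <- setdiff(set_R$genes, set_S$genes)
    only_S <- setdiff(set_S$genes, set_R$genes)
    stop("gene sets differ between conditions; only in R: {",
         paste(utils::head(only_R, 5), collapse = ", "), "}, only in S: {",
         paste(utils::head(only_S, 5), collapse = ", "), "}",
         if (length(only_R) + length(only_S) == 0)
           " (same genes, different order)" else "",
         call. = FALSE)
  }
  check_scalar_number(lfdr_threshold, "lfdr_threshold", positive = TRUE)
  genes <- set_R$genes
  g <- length(genes)
  if (g < 2L) stop("need >= 2 genes to form a pair", call. = FALSE)

  # upper triangle (i < j) in column-major order
  ut <- upper.tri(set_R$r)
  idx <- which(ut, arr.ind = TRUE)
  a <- genes[idx[, "row"]]
  b <- genes[idx[, "col"]]
  flip <- a > b  # enforce lexicographic storage order
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp

  delta <- delta_statistic(set_R$z[ut], set_S$z[ut], set_R$n, set_S$n)
  p <- edge_pvalue(delta)
  lf <- if (length(unique(delta)) == 1L) {
    # e.g. identical matrices in both conditions: no evidence anywhere
    structure(rep(1, length(delta)), eta0 = 1, scale = NA_real_)
  } else if (lfdr_input == "delta") {
    local_fdr(delta, input = "delta")
  } else {
    local_fdr(p, input = "pvalue")
  }
  edges <- data.frame(
    gene_a = a, gene_b = b,
    r_R = set_R$r[ut], r_S = set_S$r[ut],
    z_R = set_R$z[ut], z_S = set_S$z[ut],
    delta = delta, p_value = p, lfdr = as.numeric(lf),
    significant = as.numeric(lf) < lfdr_threshold,
    sign = sign(delta),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("diffcorr_edges", "data.frame"),
            n_R = set_R$n, n_S = set_S$n,
            eta0 = attr(lf, "eta0"), null_scale = attr(lf, "scale"),
            lfdr_threshold = lfdr_threshold, genes = genes)
}

#' Write a differential edge table as TSV
#'
#' Columns, in order: gene_a, gene_b, r_R, r_S, z_R, z_S, delta, p_value,
#' lfdr, significant, sign. Floats are written at 6 significant digits and
#' `significant` as `true`/`false`, so reruns are byte-identical.
#'
#' @param edges a `diffcorr_edges` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  num_cols <- c("r_R", "r_S", "z_R", "z_S", "delta", "p_value", "lfdr")
  out <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                    stringsAsFactors = FALSE)
  for (cc in num_cols) out[[cc]] <- format_num(edges[[cc]])
  out$significant <- ifelse(edges$significant, "true", "false")
  out$sign <- as.integer(edges$sign)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Delta statistics of an edge table as a symmetric matrix
#'
#' @param edges a `diffcorr_edges` data frame.
#' @return symmetric gene-by-gene matrix of delta values, zero diagonal.
#' @export
delta_matrix <- function(edges) {
  genes <- attr(edges, "genes")
  if (is.null(genes)) genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  m <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  m[cbind(ia, ib)] <- edges$delta
  m[cbind(ib, ia)] <- edges$delta
  m
}
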