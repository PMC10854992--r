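# Planted-module synthetic expression generator.
#
# Genes are partitioned into correlation modules. Within module m, in
# condition c, each gene follows the single-factor model
#   x_g = baseline_mean + noise_sd * (sqrt(rho_c[m]) * f_m + sqrt(1 - rho_c[m]) * eps_g)
# with f_m (one per module and sample) and eps_g independent standard
# normals, so the expected pairwise within-module Pearson correlation is
# exactly rho_c[m]. Background genes are pure noise. The factor model gives
# analytically known correlations, which is what makes recovery testable.

#' Specify a two-condition planted-module synthetic dataset
#'
#' Describes a pair of expression matrices ("R" = resistant, "S" =
#' sensitive) whose within-module correlation structure differs between
#' conditions in a known way. Defaults mirror a two-condition design with
#' 6 samples per condition (2 replicates x 3 time points) on a
#' variance-stabilized-like scale.
#'
#' @param n_genes total number of genes (positive integer).
#' @param module_sizes integer vector of module sizes; their sum must not
#'   exceed `n_genes`; remaining genes are independent background.
#' @param rho_R,rho_S per-module within-module correlation targets in
#'   `[0, 1)`, one per module, for conditions R and S.
#' @param n_samples_R,n_samples_S samples per condition (default 6 each).
#' @param baseline_mean mean expression level (default 8, vst-like scale).
#' @param noise_sd per-gene standard deviation (default 1).
#' @param seed integer seed; the same spec and seed reproduce the matrices
#'   bit-identically.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_expression_pair()]
#' @export
#' @examples
#' sp <- synthetic_spec(n_genes = 50, module_sizes = c(20, 20),
#'                      rho_R = c(0.8, 0.8), rho_S = c(0.0, 0.8), seed = 1)
#' sp
synthetic_spec <- function(n_genes,
                           module_sizes = integer(0),
                           rho_R = numeric(0),
                           rho_S = numeric(0),
                           n_samples_R = 6L,
                           n_samples_S = 6L,
                           baseline_mean = 8.0,
                           noise_sd = 1.0,
                           seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(module_sizes) > 0) {
    module_sizes <- vapply(seq_along(module_sizes), function(i)
      check_count(module_sizes[i], sprintf("module_sizes[%d]", i)), integer(1))
  } else {
    module_sizes <- integer(0)
  }
  if (sum(module_sizes) > n_genes) {
    stop("`module_sizes` must sum to at most `n_genes`", call. = FALSE)
  }
  k <- length(module_sizes)
  if (length(rho_R) != k || length(rho_S) != k) {
    stop("`rho_R` and `rho_S` must each have one entry per module_sizes entry",
         call. = FALSE)
  }
  for (nm in c("rho_R", "rho_S")) {
    rho <- get(nm)
    if (k > 0 && (!is.numeric(rho) || any(!is.finite(rho)) ||
                  any(rho < 0) || any(rho >= 1))) {
      stop(sprintf("`%s` entries must lie in [0, 1)", nm), call. = FALSE)
    }
  }
  n_samples_R <- check_count(n_samples_R, "n_samples_R", min = 2L)
  n_samples_S <- check_count(n_samples_S, "n_samples_S", min = 2L)
  check_scalar_number(baseline_mean, "baseline_mean")
  check_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)

  structure(
    list(n_genes = n_genes, module_sizes = module_sizes,
         rho_R = as.numeric(rho_R), rho_S = as.numeric(rho_S),
         n_samples_R = n_samples_R, n_samples_S = n_samples_S,
         baseline_mean = baseline_mean, noise_sd = noise_sd,
         seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Planted-module synthetic spec\n")
  cat(sprintf("  %d genes (%d in %d modules, %d background)\n",
              x$n_genes, sum(x$module_sizes), length(x$module_sizes),
              x$n_genes - sum(x$module_sizes)))
  if (length(x$module_sizes)) {
    cat(sprintf("  module sizes: %s\n", paste(x$module_sizes, collapse = ", ")))
    cat(sprintf("  rho_R: %s | rho_S: %s\n",
                paste(x$rho_R, collapse = ", "),
                paste(x$rho_S, collapse = ", ")))
  }
  cat(sprintf("  samples: R = %d, S = %d; baseline %.2f, noise sd %.2f; seed %d\n",
              x$n_samples_R, x$n_samples_S, x$baseline_mean, x$noise_sd,
              x$seed))
  invisible(x)
}

module_labels_for <- function(spec) {
  labels <- integer(spec$n_genes)
  if (length(spec$module_sizes)) {
    labels[seq_len(sum(spec$module_sizes))] <-
      rep(seq_along(spec$module_sizes), times = spec$module_sizes)
  }
  labels
}

simulate_condition <- function(spec, rho, n_samples) {
  labels <- module_labels_for(spec)
  x <- matrix(stats::rnorm(spec$n_genes * n_samples, mean = 0, sd = 1),
              nrow = spec$n_genes, ncol = n_samples)
  if (length(spec$module_sizes)) {
    factors <- matrix(stats::rnorm(length(spec$module_sizes) * n_samples),
                      nrow = length(spec$module_sizes), ncol = n_samples)
    for (m in seq_along(spec$module_sizes)) {
      idx <- which(labels == m)
      x[idx, ] <- sqrt(rho[m]) * matrix(factors[m, ], length(idx), n_samples,
                                        byrow = TRUE) +
        sqrt(1 - rho[m]) * x[idx, ]
    }
  }
  spec$baseline_mean + spec$noise_sd * x
}

#' Generate a two-condition expression pair with planted structure
#'
#' Draws the R and S expression matrices described by a [synthetic_spec()],
#' independently per condition, together with the ground-truth module labels.
#'
#' @param spec a `synthetic_spec`.
#' @return a list with components:
#'   \describe{
#'     \item{expr_R, expr_S}{gene-by-sample numeric matrices with stable gene
#'       names (`"G0001"` ...) and condition-tagged sample names.}
#'     \item{truth}{data frame with columns `gene`, `module` (0 =
#'       background) and `differential` (`TRUE` where `rho_R != rho_S` for
#'       the gene's module).}
#'   }
#' @export
#' @examples
#' sim <- generate_expression_pair(
#'   synthetic_spec(30, module_sizes = 10, rho_R = 0.8, rho_S = 0, seed = 7))
#' dim(sim$expr_R)
#' table(sim$truth$module)
generate_expression_pair <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be created by synthetic_spec()", call. = FALSE)
  }
  genes <- default_gene_names(spec$n_genes)
  out <- with_seed(spec$seed, {
    r <- simulate_condition(spec, spec$rho_R, spec$n_samples_R)
    s <- simulate_condition(spec, spec$rho_S, spec$n_samples_S)
    list(r = r, s = s)
  })
  dimnames(out$r) <- list(genes, sample_names_for("R", spec$n_samples_R))
  dimnames(out$s) <- list(genes, sample_names_for("S", spec$n_samples_S))
  labels <- module_labels_for(spec)
  differential <- rep(FALSE, spec$n_genes)
  if (length(spec$module_sizes)) {
    diff_mod <- spec$rho_R != spec$rho_S
    differential[labels > 0] <- diff_mod[labels[labels > 0]]
  }
  truth <- data.frame(gene = genes, module = labels,
                      differential = differential,
                      stringsAsFactors = FALSE)
  list(expr_R = out$r, expr_S = out$s, truth = truth)
}

#' Generate a matched null pair (no differential signal)
#'
#' Both conditions are drawn from the same independent-gene distribution, so
#' every gene pair is null by construction. Used to calibrate the local-FDR
#' edge selection.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_samples samples per condition; must exceed 3 because the
#'   difference statistic's variance term `1/(n - 3)` is undefined otherwise.
#' @param seed integer seed.
#' @param baseline_mean,noise_sd location and scale of the iid normal draws.
#' @return list with `expr_R` and `expr_S` matrices.
#' @export
generate_null_pair <- function(n_genes, n_samples, seed,
                               baseline_mean = 8.0, noise_sd = 1.0) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  if (n_samples <= 3L) {
    stop("`n_samples` must be > 3: the difference statistic divides by ",
         "sqrt(1/(n - 3) + 1/(n - 3))", call. = FALSE)
  }
  spec <- synthetic_spec(n_genes, n_samples_R = n_samples,
                         n_samples_S = n_samples,
                         baseline_mean = baseline_mean, noise_sd = noise_sd,
                         seed = seed)
  sim <- generate_expression_pair(spec)
  list(expr_R = sim$expr_R, expr_S = sim$expr_S)
}

#' Generate a count matrix with controlled retention failures
#'
#' Produces a non-negative integer count matrix in which a chosen subset of
#' genes has nonzero counts in fewer than half the samples, so that the
#' low-count retention filter removes a known set of genes.
#'
#' For gene g with target zero fraction t, exactly `round(t * n_samples)`
#' randomly placed samples are set to zero; the rest draw Poisson(10) + 1
#' counts (always >= 1). A gene therefore fails the default retention rule
#' ("at least 1 count in at least half the samples") iff t > 0.5.
#'
#' @param n_genes,n_samples matrix dimensions (positive integers).
#' @param zero_fraction_targets numeric vector in `[0, 1]`, recycled across
#'   genes: target fraction of forced-zero samples per gene.
#' @param seed integer seed.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
#' @examples
#' cm <- generate_count_matrix(100, 20, zero_fraction_targets = c(0, 0.75),
#'                             seed = 5)
#' sum(rowSums(cm >= 1) < 10)  # genes that will fail the filter
generate_count_matrix <- function(n_genes, n_samples, zero_fraction_targets,
                                  seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples")
  zf <- as.numeric(zero_fraction_targets)
  if (length(zf) == 0 || any(!is.finite(zf)) || any(zf < 0) || any(zf > 1)) {
    stop("`zero_fraction_targets` must be numbers in [0, 1]", call. = FALSE)
  }
  zf <- rep_len(zf, n_genes)
  counts <- with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * n_samples, lambda = 10) + 1L,
                nrow = n_genes, ncol = n_samples)
    for (g in seq_len(n_genes)) {
      n_zero <- round(zf[g] * n_samples)
      if (n_zero > 0) {
        m[g, sample.int(n_samples, n_zero)] <- 0L
      }
    }
    m
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(default_gene_names(n_genes),
                           sprintf("s%03d", seq_len(n_samples)))
  counts
}
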