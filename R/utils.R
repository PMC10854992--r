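# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace; the matching rule used for
#' every symbol comparison in the package.
#'
#' @param x character vector of gene symbols.
#' @return canonicalized character vector.
#' @export
#' @examples
#' canonicalize_symbols(c(" irf1 ", "Stat1"))
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# must_be_* validators --------------------------------------------------

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# matrix helpers --------------------------------------------------------

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}

default_gene_names <- function(n) {
  sprintf("G%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}

sample_names_for <- function(condition, n) {
  if (n == 6L) {
    # two replicates x three time points, the study's per-condition layout
    paste(condition, rep(paste0("t", 1:3), each = 2), c("a", "b"), sep = "_")
  } else {
    sprintf("%s_s%03d", condition, seq_len(n))
  }
}
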