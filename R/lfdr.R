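# Local false discovery rate with an empirical null.
#
# lfdr(x) = eta0 * f0(x) / f(x): the posterior probability that an edge
# statistic x arose from the null component. f is a Grenander (monotone
# decreasing) density estimate on the magnitude scale, f0 an empirical null
# -- half-normal with scale fit by truncated maximum likelihood on the
# central portion of the data (so an over-dispersed null inflates f0 rather
# than flooding the tail with false positives) -- and eta0 the estimated
# null proportion, capped at 1.

# Grenander estimator: slopes of the least concave majorant of the ECDF.
# Returns the density evaluated at each input point (support starts at
# `origin`). Atoms at the origin receive +Inf; callers rely on the antitonic
# post-adjustment to regularize those.
grenander_density <- function(x, origin = 0, close_at = NULL) {
  m <- length(x)
  ux <- sort(unique(x))
  cnt <- tabulate(match(x, ux), nbins = length(ux))
  px <- c(origin, ux)
  pf <- c(0, cumsum(cnt) / m)
  if (!is.null(close_at) && max(ux) < close_at) {
    px <- c(px, close_at)
    pf <- c(pf, 1)
  }
  # upper concave hull of (px, pf), scanning left to right
  hull <- integer(length(px))
  hull[1] <- 1L
  h <- 1L
  for (i in 2:length(px)) {
    while (h >= 2L) {
      s_new <- (pf[i] - pf[hull[h]]) / (px[i] - px[hull[h]])
      s_old <- (pf[hull[h]] - pf[hull[h - 1L]]) / (px[hull[h]] - px[hull[h - 1L]])
      if (s_new >= s_old) h <- h - 1L else break
    }
    h <- h + 1L
    hull[h] <- i
  }
  hull <- hull[seq_len(h)]
  hx <- px[hull]
  slopes <- diff(pf[hull]) / diff(hx)   # non-increasing by construction
  # segment k covers (hx[k], hx[k + 1]]
  seg <- findInterval(x, hx, left.open = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > length(slopes)] <- length(slopes)
  slopes[seg]
}

# Truncated-ML fit of the half-normal null scale on observations <= x0.
fit_halfnormal_scale <- function(ax, x0) {
  central <- ax[ax <= x0]
  if (length(central) < 3L || stats::sd(central) == 0) {
    return(max(stats::sd(ax), .Machine$double.eps))
  }
  negll <- function(s) {
    length(central) * (log(s) + log(2 * stats::pnorm(x0 / s) - 1)) +
      sum(central^2) / (2 * s^2)
  }
  upper <- max(3 * stats::sd(ax), x0, 1e-2)
  stats::optimize(negll, interval = c(1e-4, upper))$minimum
}

#' Local false discovery rate of difference statistics
#'
#' Estimates, for each statistic, the posterior probability of being null,
#' from the mixture `f(x) = eta0 * f0(x) + (1 - eta0) * f1(x)` fit on the
#' magnitude scale.
#'
#' With `input = "delta"` (the default) the null `f0` is a half-normal on
#' `|delta|` whose scale is fit by truncated maximum likelihood on the
#' central 75% of the data, `f` is a Grenander (monotone) density estimate,
#' and `eta0` is the implied null proportion, capped at 1. With
#' `input = "pvalue"` the values are p-values, the null is uniform on
#' `[0, 1]` and `eta0` comes from the upper-quartile tail. Either way the
#' result is clipped to `[0, 1]` and made monotone in the evidence
#' (non-increasing in `|delta|`, non-decreasing in p) by an isotonic
#' adjustment.
#'
#' @param x numeric vector: delta statistics (any sign) or p-values.
#' @param input `"delta"` or `"pvalue"`.
#' @return numeric vector of lfdr values in `[0, 1]`, in input order, with
#'   attributes `eta0` (estimated null proportion) and, for delta input,
#'   `scale` (fitted half-normal null scale).
#' @references Efron-style empirical-null local fdr; Grenander decreasing
#'   density estimation via the least concave majorant of the ECDF.
#' @export
#' @examples
#' set.seed(1)
#' d <- c(rnorm(950), rnorm(50, mean = 5))
#' lf <- local_fdr(d)
#' attr(lf, "eta0")
local_fdr <- function(x, input = c("delta", "pvalue")) {
  input <- match.arg(input)
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x))) {
    stop("`x` must be >= 2 finite numeric values", call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    stop("degenerate statistic distribution: all values identical",
         call. = FALSE)
  }
  if (length(x) < 50L) {
    warning("local_fdr() with fewer than 50 values is unreliable",
            call. = FALSE)
  }

  if (input == "delta") {
    ax <- abs(x)
    x0 <- stats::quantile(ax, 0.75, names = FALSE)
    if (x0 <= 0) x0 <- min(ax[ax > 0])
    s0 <- fit_halfnormal_scale(ax, x0)
    p_null_central <- 2 * stats::pnorm(x0 / s0) - 1
    eta0 <- min(1, mean(ax <= x0) / p_null_central)
    f <- grenander_density(ax, origin = 0)
    f0 <- 2 * stats::dnorm(ax, mean = 0, sd = s0)
    lf <- pmin(1, pmax(0, eta0 * f0 / f))
    lf <- pmin(1, pmax(0, antitonic_in(ax, lf)))
    attr(lf, "scale") <- s0
  } else {
    if (any(x < 0) || any(x > 1)) {
      stop("p-value input must lie in [0, 1]", call. = FALSE)
    }
    lambda <- 0.75
    eta0 <- min(1, mean(x > lambda) / (1 - lambda))
    if (eta0 == 0) eta0 <- 1 / (length(x) * (1 - lambda))
    f <- grenander_density(x, origin = 0, close_at = 1)
    lf <- pmin(1, pmax(0, eta0 / f))
    lf <- pmin(1, pmax(0, -antitonic_in(x, -lf)))  # non-decreasing in p
  }
  attr(lf, "eta0") <- eta0
  lf
}

# Least-squares monotone non-increasing fit of y against x, returned in the
# original order of x.
antitonic_in <- function(x, y) {
  fit <- stats::isoreg(x, -y)
  out <- numeric(length(y))
  ord <- fit$ord
  if (is.null(ord)) ord <- seq_along(y)
  out[ord] <- -fit$yf
  out
}
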