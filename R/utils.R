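#' Logit with clamping
#'
#' Divergence transforms clamp before taking logs so that estimates at or
#' beyond the boundary (F_ST of 0 or 1, d_XY of 0) stay finite on the
#' modeling scale while the raw values are kept unchanged elsewhere.
#'
#' @param p numeric vector of proportions.
#' @param eps clamp width; values are forced into `[eps, 1 - eps]`.
#' @return `log(p/(1-p))` after clamping.
#' @export
logit_clamped <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' log10 with a floor
#' @param x non-negative numeric vector.
#' @param eps floor applied before taking log10.
#' @return `log10(pmax(x, eps))`.
#' @export
log10_floored <- function(x, eps = 1e-6) {
  log10(pmax(x, eps))
}

#' Bias-corrected percentile bootstrap CI of a mean
#'
#' Resamples the vector with replacement `B` times and returns the
#' bias-corrected (BC) percentile interval of the mean. The bias correction
#' shifts the percentile points by `2*z0` where `z0 = qnorm(P(boot < est))`;
#' for a symmetric bootstrap distribution it reduces to the plain
#' percentile interval.
#'
#' @param x numeric vector (NAs dropped).
#' @param B number of bootstrap resamples.
#' @param conf confidence level.
#' @return list with `mean`, `lower`, `upper`, `B`.
#' @export
boot_mean_ci <- function(x, B = 2000L, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("boot_mean_ci: no finite values")
  est <- mean(x)
  if (n == 1L || all(x == x[1L])) {
    return(list(mean = est, lower = est, upper = est, B = B))
  }
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  boots <- colMeans(matrix(x[idx], nrow = n))
  # bias-correction factor; clamp the proportion away from {0,1}
  prop <- (sum(boots < est) + 0.5 * sum(boots == est)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  a <- qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  probs <- pnorm(2 * z0 + a)
  ci <- unname(quantile(boots, probs, type = 7))
  list(mean = est, lower = ci[1L], upper = ci[2L], B = B)
}

#' Equal-count quantile bins with deterministic tie-breaking
#'
#' Assigns each value to one of `n_bins` equal-count bins. Ties are broken
#' by a stable sort on `(value, id)` so bin membership is reproducible;
#' marginal counts differ by at most one.
#'
#' @param x numeric vector, all finite.
#' @param id tie-breaking key (default element order).
#' @param n_bins number of bins.
#' @return integer vector of bin indices in `1:n_bins`.
#' @export
quantile_bins <- function(x, id = seq_along(x), n_bins = 8L) {
  stopifnot(all(is.finite(x)), length(x) >= n_bins)
  ord <- order(x, id)
  n <- length(x)
  # distribute n over n_bins as evenly as possible
  sizes <- rep(n %/% n_bins, n_bins) + c(rep(1L, n %% n_bins),
                                         rep(0L, n_bins - n %% n_bins))
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(n_bins), sizes)
  bins
}

# derive a child seed from a base seed and a stage offset, kept < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
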