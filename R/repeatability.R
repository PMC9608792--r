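#' Repeatability of per-gene divergence across population pairs
#'
#' Two complementary summaries of how much per-gene divergence is shared
#' across the three population pairs:
#' * a principal component analysis of the three aligned per-gene vectors
#'   (columns centered, unscaled: covariance PCA), returning the fraction
#'   of variance on PC1 and its loadings;
#' * the one-way ANOVA intraclass correlation ICC(1) with gene as the
#'   factor: `R = (MS_B - MS_W) / (MS_B + (k-1) MS_W)` with `k` the number
#'   of pairs. Negative estimates are reported as-is.
#'
#' @param m numeric matrix (or data.frame) with one column per population
#'   pair and one row per gene, aligned on a shared gene index. Rows with
#'   any missing value are dropped listwise.
#' @param scale. set `TRUE` for correlation-matrix PCA (default covariance).
#' @return list with `pc1_variance_fraction`, `pc1_loadings`, `icc_R`,
#'   `F`, `df`, `p`, `MS_between`, `MS_within`, `n_genes`, `k`.
#' @export
repeatability <- function(m, scale. = FALSE) {
  m <- as.matrix(m)
  k <- ncol(m)
  stopifnot(k >= 2L)
  m <- m[stats::complete.cases(m) & rowSums(!is.finite(m)) == 0L, ,
         drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("repeatability: need >= 3 complete genes")
  constant_cols <- apply(m, 2L, sd) == 0
  pca <- if (all(m == m[, 1L])) {
    # identical columns: covariance matrix is rank one by construction
    list(frac = 1, load = rep(1 / sqrt(k), k))
  } else {
    pr <- prcomp(m, center = TRUE, scale. = scale.)
    v <- pr$sdev^2
    load <- pr$rotation[, 1L]
    if (mean(load) < 0) load <- -load
    list(frac = v[1L] / sum(v), load = unname(load))
  }
  gm <- mean(m)
  row_means <- rowMeans(m)
  ss_b <- k * sum((row_means - gm)^2)
  ss_w <- sum((m - row_means)^2)
  df_b <- n - 1L
  df_w <- n * (k - 1L)
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  icc <- if (ms_b + (k - 1) * ms_w == 0) NaN else {
    (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  }
  f_stat <- if (ms_w == 0) Inf else ms_b / ms_w
  list(pc1_variance_fraction = pca$frac, pc1_loadings = pca$load,
       pc1_scores = if (all(m == m[, 1L])) m[, 1L] - mean(m[, 1L]) else
         prcomp(m, center = TRUE, scale. = scale.)$x[, 1L],
       icc_R = icc, F = f_stat, df = c(df_b, df_w),
       p = pf(f_stat, df_b, df_w, lower.tail = FALSE),
       MS_between = ms_b, MS_within = ms_w, n_genes = n, k = k,
       constant_cols = constant_cols)
}

#' Binned divergence surface over two Tajima's D axes
#'
#' Bins genes into `n_bins` equal-count groups along the standardized D of
#' each population (ties broken by gene id), and reports the mean of a
#' divergence statistic in each of the `n_bins x n_bins` cells, with cell
#' counts and quantile edges. Cells with fewer than `min_cell` genes are
#' flagged.
#'
#' @param d1,d2 standardized Tajima's D of the two populations.
#' @param stat statistic to average per cell (e.g. raw or logit F_ST).
#' @param gene_id tie-breaking id (default element order).
#' @param n_bins bins per axis.
#' @param min_cell flag threshold for thin cells.
#' @return object of class `bin_surface`: list with `edges1`, `edges2`
#'   (quantile edges), `mean` and `count` (`n_bins x n_bins` matrices,
#'   rows = d1 bins), `flagged` (logical matrix), `marginal1`, `marginal2`.
#' @export
bin_surface <- function(d1, d2, stat, gene_id = seq_along(d1),
                        n_bins = 8L, min_cell = 5L) {
  ok <- is.finite(d1) & is.finite(d2) & is.finite(stat)
  d1 <- d1[ok]; d2 <- d2[ok]; stat <- stat[ok]
  gene_id <- gene_id[ok]
  n <- length(d1)
  if (n < n_bins^2) stop("bin_surface: need >= ", n_bins^2, " genes")
  b1 <- quantile_bins(d1, gene_id, n_bins)
  b2 <- quantile_bins(d2, gene_id, n_bins)
  mean_m <- matrix(NaN, n_bins, n_bins)
  count_m <- matrix(0L, n_bins, n_bins)
  sums <- tapply(stat, list(factor(b1, 1:n_bins), factor(b2, 1:n_bins)), sum)
  cnts <- table(factor(b1, 1:n_bins), factor(b2, 1:n_bins))
  count_m[] <- as.integer(cnts)
  has <- count_m > 0L
  mean_m[has] <- as.numeric(sums)[has] / count_m[has]
  out <- list(edges1 = quantile(d1, probs = seq(0, 1, length.out = n_bins + 1)),
              edges2 = quantile(d2, probs = seq(0, 1, length.out = n_bins + 1)),
              mean = mean_m, count = count_m,
              flagged = count_m < min_cell,
              marginal1 = tabulate(b1, n_bins),
              marginal2 = tabulate(b2, n_bins),
              n = n, n_bins = n_bins)
  class(out) <- "bin_surface"
  out
}

#' @export
print.bin_surface <- function(x, ...) {
  cat(sprintf("<bin_surface> %dx%d cells over %d genes (%d thin cells)\n",
              x$n_bins, x$n_bins, x$n, sum(x$flagged)))
  invisible(x)
}
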