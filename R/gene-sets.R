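#' Select genes with imbalanced selection signals and high divergence
#'
#' The footprint gene set: genes whose Tajima's D differs strongly between
#' the two populations (sweep-like spectrum in one, balancing-like in the
#' other) while the pair's F_ST exceeds a threshold. Both inequalities are
#' strict. By default the standardized D used in the models is thresholded;
#' set `use_std = FALSE` for raw D.
#'
#' @param table per-gene pair table with `gene_id`, `fst` (raw scale) and
#'   `D1_std`/`D2_std` (or `D1_raw`/`D2_raw` when `use_std = FALSE`).
#' @param d_diff threshold on `|D1 - D2|`.
#' @param fst_min threshold on raw F_ST.
#' @param use_std threshold standardized (default) or raw D.
#' @return object of class `imbalance_set`: list with `genes` (character,
#'   sorted), `d_diff`, `fst_min`, `n`, `n_candidates`.
#' @export
select_imbalance <- function(table, d_diff = 2.5, fst_min = 0.3,
                             use_std = TRUE) {
  d1 <- if (use_std) table$D1_std else table$D1_raw
  d2 <- if (use_std) table$D2_std else table$D2_raw
  ok <- is.finite(d1) & is.finite(d2) & is.finite(table$fst)
  sel <- ok & abs(d1 - d2) > d_diff & table$fst > fst_min
  out <- list(genes = sort(table$gene_id[sel]), d_diff = d_diff,
              fst_min = fst_min, n = sum(sel), n_candidates = sum(ok))
  class(out) <- "imbalance_set"
  out
}

#' @export
print.imbalance_set <- function(x, ...) {
  cat(sprintf("<imbalance_set> %d genes (|dD| > %.2f & F_ST > %.2f of %d candidates)\n",
              x$n, x$d_diff, x$fst_min, x$n_candidates))
  invisible(x)
}

#' Hypergeometric over-representation of terms in a gene set
#'
#' Upper-tail hypergeometric test per term: with `N` universe genes of
#' which `K` carry the term, and a set of `n` genes of which `k` carry it,
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Raw p-values are
#' thresholded by default (no multiple-testing correction, mirroring
#' GOstats-style usage); set `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param set character vector of gene ids (must be a subset of `universe`).
#' @param universe character vector of gene ids.
#' @param term_map named list mapping term id to gene ids (see
#'   [read_term_map()]); terms with no universe gene are skipped.
#' @param p_cut retain rows with (adjusted) p below this cutoff.
#' @param min_genes retain rows with at least this many set genes.
#' @param adjust apply Benjamini-Hochberg correction before the cutoff.
#' @return data.frame sorted by p then term_id with columns `term_id`,
#'   `k`, `K`, `n`, `N`, `p` (and `p_adj` when `adjust = TRUE`).
#' @export
hypergeom_enrichment <- function(set, universe, term_map, p_cut = 0.05,
                                 min_genes = 2L, adjust = FALSE) {
  set <- unique(set)
  universe <- unique(universe)
  if (!all(set %in% universe)) stop("gene set is not a subset of the universe")
  N <- length(universe)
  n <- length(set)
  rows <- lapply(names(term_map), function(tid) {
    tg <- intersect(term_map[[tid]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (adjust) out$p_adj <- p.adjust(out$p, method = "BH")
  crit <- if (adjust) out$p_adj else out$p
  out <- out[crit < p_cut & out$k >= min_genes, , drop = FALSE]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a gene class against its complement
#'
#' Welch's unequal-variance t-test of a transformed divergence response
#' between genes of a class and all other genes, with a bias-corrected
#' percentile bootstrap CI of each class mean (resampling genes within
#' class) and an optional label-permutation p-value for the mean
#' difference.
#'
#' @param values numeric response (e.g. `fst_logit` or `dxy_log10`) for all
#'   genes.
#' @param in_class logical vector: class membership, aligned with `values`.
#' @param B bootstrap resamples for the class-mean CIs.
#' @param n_perm label permutations (0 skips the permutation test).
#' @param seed RNG seed for bootstrap/permutation reproducibility.
#' @param min_class minimum finite class members.
#' @return list with `mean_in`, `mean_out`, `ci_in`, `ci_out` (each
#'   `c(lower, upper)`), `t`, `df`, `p`, `p_perm` (NA when skipped),
#'   `n_in`, `n_out`.
#' @export
class_compare <- function(values, in_class, B = 2000L, n_perm = 0L,
                          seed = NULL, min_class = 5L) {
  stopifnot(length(values) == length(in_class))
  ok <- is.finite(values)
  x <- values[ok & in_class]
  y <- values[ok & !in_class]
  if (length(x) < min_class) stop("class has fewer than ", min_class,
                                  " members with finite response")
  if (!is.null(seed)) set.seed(seed)
  tt <- t.test(x, y)   # Welch by default
  ci_in <- boot_mean_ci(x, B = B)
  ci_out <- boot_mean_ci(y, B = B)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    obs <- mean(x) - mean(y)
    pool <- c(x, y)
    nx <- length(x)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nx)
      d <- mean(pool[idx]) - mean(pool[-idx])
      if (abs(d) >= abs(obs)) hits <- hits + 1L
    }
    p_perm <- (hits + 1L) / (n_perm + 1L)
  }
  list(mean_in = mean(x), mean_out = mean(y),
       ci_in = c(ci_in$lower, ci_in$upper),
       ci_out = c(ci_out$lower, ci_out$upper),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_perm = p_perm,
       n_in = length(x), n_out = length(y))
}

# one-way F statistic from a response and an integer group vector
oneway_F <- function(y, g, k) {
  n <- length(y)
  sums <- tapply(y, factor(g, seq_len(k)), sum)
  cnts <- tabulate(g, k)
  gm <- sum(y) / n
  ss_b <- sum(sums^2 / cnts) - n * gm^2
  ss_t <- sum(y^2) - n * gm^2
  ss_w <- ss_t - ss_b
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Divergence across sex-bias expression bins
#'
#' Genes with female-biased (FBG) and male-biased (MBG) expression are each
#' split into four equal-count bins by the magnitude of their log2
#' fold-change (female minus male convention), giving eight bins. A one-way
#' F statistic of the transformed divergence response across the eight bins
#' is referred to its label-permutation distribution (add-one corrected
#' p-value). Per-bin means carry bias-corrected bootstrap CIs.
#'
#' @param expression expression table (see [read_expression()]).
#' @param table per-gene pair table with `gene_id` and the response column.
#' @param response name of the response column (e.g. `"fst_logit"`).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param B bootstrap resamples per bin.
#' @return list with `bins` (data.frame: `bias_class`, `quartile`, `n`,
#'   `mean`, `lower`, `upper`), `F`, `p_perm`, `n_genes`.
#' @export
sexbias_bins <- function(expression, table, response = "fst_logit",
                         n_perm = 10000L, seed = 1L, B = 2000L) {
  stopifnot(response %in% names(table))
  m <- merge(expression, table[, c("gene_id", response)], by = "gene_id")
  m <- m[m$bias_class %in% c("FBG", "MBG") & is.finite(m[[response]]) &
           is.finite(m$log2fc_sex), , drop = FALSE]
  if (nrow(m) < 16L) stop("sexbias_bins: too few sex-biased genes")
  m$quartile <- NA_integer_
  for (bc in c("FBG", "MBG")) {
    i <- m$bias_class == bc
    if (sum(i) < 4L) stop("sexbias_bins: fewer than 4 ", bc, " genes")
    m$quartile[i] <- quantile_bins(abs(m$log2fc_sex[i]), m$gene_id[i], 4L)
  }
  m$bin <- (as.integer(m$bias_class == "MBG")) * 4L + m$quartile
  cnts <- tabulate(m$bin, 8L)
  if (any(cnts < 2L)) stop("sexbias_bins: a bin has fewer than 2 genes")
  set.seed(seed)
  y <- m[[response]]
  f_obs <- oneway_F(y, m$bin, 8L)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (oneway_F(y, sample(m$bin), 8L) >= f_obs) hits <- hits + 1L
  }
  p_perm <- (hits + 1L) / (n_perm + 1L)
  bins <- do.call(rbind, lapply(1:8, function(b) {
    ci <- boot_mean_ci(y[m$bin == b], B = B)
    data.frame(bias_class = if (b <= 4L) "FBG" else "MBG",
               quartile = ((b - 1L) %% 4L) + 1L, n = cnts[b],
               mean = ci$mean, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  }))
  list(bins = bins, F = f_obs, p_perm = p_perm, n_genes = nrow(m))
}
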