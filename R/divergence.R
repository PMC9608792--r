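#' Join two pools into per-site biallelic counts
#'
#' Restricts to classified sites whose nucleotide depth falls inside the
#' depth window in *both* pools, reduces each site to the two
#' highest-count alleles summed across the pair (the divergence statistics
#' are biallelic), and flags SNPs. A site is a SNP for the pair when, after
#' reduction, some pool carries the alternative allele with at least
#' `min_minor_count` reads, or the two pools are fixed for different
#' alleles. Sub-threshold minor counts are zeroed when computing allele
#' frequencies so such sites behave as monomorphic, but raw counts are kept
#' for the identity-probability estimators.
#'
#' @inheritParams filter_sites
#' @param pool_x,pool_y pool indices of the two populations.
#' @return data.frame with one row per retained site: `gene_id`, `pos`,
#'   `cx1`, `cx2`, `cy1`, `cy2` (reads for the two retained alleles),
#'   `ax`, `ay` (pool read frequencies of allele 1 after thresholding),
#'   `is_snp`, plus attributes `n_pool_x`, `n_pool_y`.
#' @export
pair_allele_counts <- function(sync, site_classes, pool_x, pool_y,
                               min_minor_count = 2L, min_depth = 10L,
                               max_depth = 500L) {
  stopifnot(inherits(sync, "sync_counts"))
  mx <- sync$counts[[pool_x]][, 1:4, drop = FALSE]
  my <- sync$counts[[pool_y]][, 1:4, drop = FALSE]
  key_sync <- paste(sync$sites$contig, sync$sites$pos)
  key_cls <- paste(site_classes$contig, site_classes$pos)
  idx <- match(key_cls, key_sync)
  keep <- !is.na(idx)
  cls <- site_classes[keep, , drop = FALSE]
  mx <- mx[idx[keep], , drop = FALSE]
  my <- my[idx[keep], , drop = FALSE]

  dx <- rowSums(mx); dy <- rowSums(my)
  ok <- dx >= min_depth & dx <= max_depth & dy >= min_depth & dy <= max_depth
  cls <- cls[ok, , drop = FALSE]
  mx <- mx[ok, , drop = FALSE]; my <- my[ok, , drop = FALSE]

  tot <- mx + my
  # indices of the two highest summed counts per site
  a1 <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(nrow(tot)), a1)] <- -1L
  a2 <- max.col(tot2, ties.method = "first")
  ii <- seq_len(nrow(tot))
  cx1 <- mx[cbind(ii, a1)]; cx2 <- mx[cbind(ii, a2)]
  cy1 <- my[cbind(ii, a1)]; cy2 <- my[cbind(ii, a2)]
  # a pool whose reads all fall outside the two retained alleles cannot be
  # used for this site
  usable <- (cx1 + cx2) >= 2L & (cy1 + cy2) >= 2L
  cls <- cls[usable, , drop = FALSE]
  cx1 <- cx1[usable]; cx2 <- cx2[usable]
  cy1 <- cy1[usable]; cy2 <- cy2[usable]

  thr <- function(c1, c2) {
    # zero the within-pool minor when below the calling threshold
    minor_is_2 <- c2 <= c1
    min_c <- pmin(c1, c2)
    drop <- min_c < min_minor_count & min_c > 0L
    c1[drop & !minor_is_2] <- 0L
    c2[drop & minor_is_2] <- 0L
    list(c1, c2)
  }
  fx <- thr(cx1, cx2); fy <- thr(cy1, cy2)
  ax <- fx[[1L]] / (fx[[1L]] + fx[[2L]])
  ay <- fy[[1L]] / (fy[[1L]] + fy[[2L]])
  poly_x <- fx[[1L]] > 0L & fx[[2L]] > 0L
  poly_y <- fy[[1L]] > 0L & fy[[2L]] > 0L
  fixed_diff <- !poly_x & !poly_y & (ax != ay)
  out <- data.frame(gene_id = cls$gene_id, pos = cls$pos,
                    cx1 = cx1, cx2 = cx2, cy1 = cy1, cy2 = cy2,
                    ax = ax, ay = ay,
                    is_snp = poly_x | poly_y | fixed_diff,
                    stringsAsFactors = FALSE)
  attr(out, "n_pool_x") <- sync$pool_sizes[pool_x]
  attr(out, "n_pool_y") <- sync$pool_sizes[pool_y]
  out
}

# unbiased within-pool identity probability from read counts
# reads resample the n pool chromosomes with replacement, so the raw read
# identity F satisfies E[F] = 1/n + (1 - 1/n) Q1; invert for Q1
q1_hat_pool <- function(c1, c2, n_pool) {
  cc <- c1 + c2
  f <- (c1 * (c1 - 1) + c2 * (c2 - 1)) / (cc * (cc - 1))
  (n_pool * f - 1) / (n_pool - 1)
}

#' Unbiased pooled F_ST for one gene
#'
#' Identity-probability estimator for pool-seq pairs. Per SNP, the
#' within-pool identity `Q1` is estimated from read identity corrected for
#' reads resampling the same pool chromosome and for finite haploid pool
#' size; the between-pool identity `Q2` is the cross-pool read identity
#' (reads from different pools never share a chromosome, so it is unbiased
#' as is). The gene estimate is the ratio of sums across SNPs:
#' `F_ST = (mean Q1 - mean Q2) / (1 - mean Q2)`.
#'
#' @param pair per-site table from [pair_allele_counts()] restricted to one
#'   gene (only rows with `is_snp` are used).
#' @param n_pool_x,n_pool_y haploid pool sizes (default: taken from the
#'   attributes of `pair`).
#' @return list with `fst`, `q1_hat`, `q2_hat`, `n_snps`. `fst` is `NaN`
#'   when the gene has no SNPs or the denominator is not positive.
#' @export
fst_gene <- function(pair, n_pool_x = attr(pair, "n_pool_x"),
                     n_pool_y = attr(pair, "n_pool_y")) {
  s <- pair[pair$is_snp, , drop = FALSE]
  n_snps <- nrow(s)
  if (n_snps == 0L) {
    return(list(fst = NaN, q1_hat = NaN, q2_hat = NaN, n_snps = 0L))
  }
  q1x <- q1_hat_pool(s$cx1, s$cx2, n_pool_x)
  q1y <- q1_hat_pool(s$cy1, s$cy2, n_pool_y)
  q2 <- (s$cx1 * s$cy1 + s$cx2 * s$cy2) /
    ((s$cx1 + s$cx2) * (s$cy1 + s$cy2))
  q1_bar <- mean((q1x + q1y) / 2)
  q2_bar <- mean(q2)
  denom <- 1 - q2_bar
  fst <- if (denom > 0) (q1_bar - q2_bar) / denom else NaN
  list(fst = fst, q1_hat = q1_bar, q2_hat = q2_bar, n_snps = n_snps)
}

#' Absolute divergence d_XY for one gene
#'
#' `d_XY = sum over sites of (A_X*B_Y + A_Y*B_X) / n_sites_total`, where A
#' and B are the pool-estimated frequencies of the two variants at a site
#' and the denominator counts all sites in the gene passing the depth
#' filters in both populations, variable or not. Monomorphic-identical
#' sites contribute 0; fixed differences contribute 1.
#'
#' @param ax,ay frequencies of allele 1 (consistent labels across the two
#'   populations) at each variable site.
#' @param n_sites_total total number of sites in the window.
#' @return d_XY in `[0, 1]`; `NaN` when `n_sites_total` is 0.
#' @export
dxy_gene <- function(ax, ay, n_sites_total) {
  if (n_sites_total == 0L) return(NaN)
  stopifnot(n_sites_total >= length(ax))
  sum(ax * (1 - ay) + ay * (1 - ax)) / n_sites_total
}

#' Add modeling-scale transforms to a divergence table
#'
#' F_ST is clamped to `[eps, 1-eps]` before the logit; d_XY is floored at
#' `eps_d` before log10. Raw values are retained; slightly negative
#' unbiased F_ST estimates stay negative in `fst` so that class means keep
#' their unbiasedness.
#'
#' @param pair_stats data.frame with columns `fst` and `dxy`.
#' @param eps clamp for the logit.
#' @param eps_d floor for the log10.
#' @return the table with `fst_logit` and `dxy_log10` columns added.
#' @export
transform_divergence <- function(pair_stats, eps = 1e-4, eps_d = 1e-6) {
  pair_stats$fst_logit <- logit_clamped(pair_stats$fst, eps)
  pair_stats$dxy_log10 <- log10_floored(pair_stats$dxy, eps_d)
  pair_stats
}

#' Per-gene divergence between two pools
#'
#' Driver joining two pools of a sync object into per-gene `PairStats`:
#' unbiased pooled F_ST (ratio of sums over SNPs), d_XY over all sites
#' passing the depth filters in both pools, and their modeling transforms.
#'
#' @inheritParams pair_allele_counts
#' @param pair label for the population pair (e.g. `"B-C"`).
#' @return data.frame with one row per gene: `gene_id`, `pair`, `fst`,
#'   `fst_logit`, `q1_hat`, `q2_hat`, `dxy`, `dxy_log10`, `n_snps`,
#'   `n_sites_total`.
#' @export
divergence_pair <- function(sync, site_classes, pool_x, pool_y,
                            pair = paste0(pool_x, "-", pool_y),
                            min_minor_count = 2L, min_depth = 10L,
                            max_depth = 500L) {
  pc <- pair_allele_counts(sync, site_classes, pool_x, pool_y,
                           min_minor_count, min_depth, max_depth)
  npx <- attr(pc, "n_pool_x"); npy <- attr(pc, "n_pool_y")
  dt <- data.table::as.data.table(pc)
  per_gene <- dt[, {
    snp <- is_snp
    q1x <- q1_hat_pool(cx1[snp], cx2[snp], npx)
    q1y <- q1_hat_pool(cy1[snp], cy2[snp], npy)
    q2 <- (cx1[snp] * cy1[snp] + cx2[snp] * cy2[snp]) /
      ((cx1[snp] + cx2[snp]) * (cy1[snp] + cy2[snp]))
    n_snps <- sum(snp)
    if (n_snps > 0L) {
      q1_bar <- mean((q1x + q1y) / 2)
      q2_bar <- mean(q2)
      fst <- if (1 - q2_bar > 0) (q1_bar - q2_bar) / (1 - q2_bar) else NaN
    } else {
      q1_bar <- NaN; q2_bar <- NaN; fst <- NaN
    }
    list(fst = fst, q1_hat = q1_bar, q2_hat = q2_bar,
         dxy = dxy_gene(ax[snp], ay[snp], .N),
         n_snps = n_snps, n_sites_total = .N)
  }, by = "gene_id"]
  out <- as.data.frame(per_gene)
  out$pair <- pair
  out <- transform_divergence(out)
  out <- out[order(out$gene_id),
             c("gene_id", "pair", "fst", "fst_logit", "q1_hat", "q2_hat",
               "dxy", "dxy_log10", "n_snps", "n_sites_total")]
  rownames(out) <- NULL
  out
}
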