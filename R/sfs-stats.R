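#' Tajima's constants for a sample of n chromosomes
#'
#' The variance-normalizer constants of Tajima's D (a1, a2, b1, b2, c1, c2,
#' e1, e2) for a sample of `n` chromosomes.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @return named list with the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Reduce sync counts to per-site pooled minor-allele data for one pool
#'
#' Drops N and deletion counts, reduces each site to its two highest-count
#' nucleotides, and applies the depth and minor-count filters:
#' * sites with total nucleotide depth outside `[min_depth, max_depth]` are
#'   dropped entirely (they count toward nothing);
#' * sites whose minor count is below `min_minor_count` are kept as
#'   monomorphic (`minor_count = 0`) so they still enter per-site totals;
#' * sites with three or more alleles at or above `min_minor_count` are
#'   dropped and counted in the `n_triallelic` attribute.
#'
#' Statistics downstream are folded (minor-allele) frequencies; no ancestral
#' polarization is attempted. The effective number of chromosomes per site is
#' `n_eff = min(haploid pool size, depth)`, the ceiling imposed by the
#' two-stage sampling of pool-seq.
#'
#' @param sync a `sync_counts` object from [read_sync()].
#' @param site_classes site-class table from [read_gene_annotation()].
#' @param pool pool index (column of the sync object).
#' @param min_minor_count minimum reads supporting the minor allele for a
#'   site to be called polymorphic.
#' @param min_depth,max_depth inclusive depth window.
#' @return data.frame with `gene_id`, `contig`, `pos`, `class`,
#'   `major_count`, `minor_count`, `depth`, `freq_hat`, `n_eff`; attribute
#'   `n_triallelic` counts dropped multi-allelic sites.
#' @export
filter_sites <- function(sync, site_classes, pool,
                         min_minor_count = 2L, min_depth = 10L,
                         max_depth = 500L) {
  stopifnot(inherits(sync, "sync_counts"),
            min_minor_count >= 1L, min_depth >= 1L, min_depth <= max_depth)
  m <- sync$counts[[pool]][, 1:4, drop = FALSE]  # A,T,C,G only
  key_sync <- paste(sync$sites$contig, sync$sites$pos)
  key_cls <- paste(site_classes$contig, site_classes$pos)
  idx <- match(key_cls, key_sync)
  keep <- !is.na(idx)
  cls <- site_classes[keep, , drop = FALSE]
  m <- m[idx[keep], , drop = FALSE]

  depth <- rowSums(m)
  in_depth <- depth >= min_depth & depth <= max_depth
  cls <- cls[in_depth, , drop = FALSE]
  m <- m[in_depth, , drop = FALSE]
  depth <- depth[in_depth]

  # top three allele counts per site, vectorized
  ii <- seq_len(nrow(m))
  w <- m
  j1 <- max.col(w, ties.method = "first"); major <- w[cbind(ii, j1)]
  w[cbind(ii, j1)] <- -1L
  j2 <- max.col(w, ties.method = "first"); minor <- w[cbind(ii, j2)]
  w[cbind(ii, j2)] <- -1L
  j3 <- max.col(w, ties.method = "first"); third <- w[cbind(ii, j3)]
  tri <- third >= min_minor_count
  n_tri <- sum(tri)
  cls <- cls[!tri, , drop = FALSE]
  major <- major[!tri]; minor <- minor[!tri]; depth <- depth[!tri]
  minor[minor < min_minor_count] <- 0L

  out <- data.frame(gene_id = cls$gene_id, contig = cls$contig,
                    pos = cls$pos, class = cls$class,
                    major_count = major, minor_count = minor,
                    depth = depth,
                    freq_hat = minor / depth,
                    n_eff = pmin(sync$pool_sizes[pool], depth),
                    stringsAsFactors = FALSE)
  attr(out, "n_triallelic") <- n_tri
  out
}

#' Tajima's estimators for one gene and site class
#'
#' @param freq_hat folded minor-allele frequencies, one per site (0 for
#'   monomorphic sites).
#' @param n_eff effective number of chromosomes used for the whole gene
#'   (the median per-site `n_eff` in the driver).
#' @return list with `S` (number of polymorphic sites), `theta_pi`
#'   (sum over sites of `2*p*(1-p) * n_eff/(n_eff-1)`), `theta_w` (`S / a1`).
#' @export
theta_estimates <- function(freq_hat, n_eff) {
  if (length(freq_hat) == 0L) return(list(S = 0L, theta_pi = 0, theta_w = 0))
  stopifnot(n_eff >= 2)
  S <- sum(freq_hat > 0)
  theta_pi <- sum(2 * freq_hat * (1 - freq_hat)) * n_eff / (n_eff - 1)
  a1 <- tajima_constants(n_eff)$a1
  list(S = as.integer(S), theta_pi = theta_pi, theta_w = S / a1)
}

#' Tajima's D from gene-level estimators
#'
#' `D = (theta_pi - theta_w) / sqrt(e1*S + e2*S*(S-1))` with the constants
#' of [tajima_constants()]. Negative values indicate an excess of rare
#' variants (sweep-like spectra), positive values an excess of
#' intermediate-frequency variants (balancing-like spectra). `NaN` is
#' returned when the gene has fewer than `min_snps` segregating sites
#' (the normalizer is unstable there).
#'
#' @param S number of segregating sites.
#' @param theta_pi,theta_w estimators from [theta_estimates()].
#' @param n_eff effective number of chromosomes (>= 4 for a finite
#'   variance term; smaller values return `NaN` with a warning).
#' @param min_snps minimum S for a finite D.
#' @return Tajima's D, or `NaN`.
#' @export
tajimas_d <- function(S, theta_pi, theta_w, n_eff, min_snps = 3L) {
  if (n_eff < 4) {
    warning("tajimas_d: n_eff < 4, returning NaN")
    return(NaN)
  }
  if (S < max(min_snps, 1L)) return(NaN)
  k <- tajima_constants(n_eff)
  denom <- k$e1 * S + k$e2 * S * (S - 1)
  (theta_pi - theta_w) / sqrt(denom)
}

#' Standardize Tajima's D across genes within a population
#'
#' Finite entries are transformed to mean 0 and unit variance; `NaN`/`NA`
#' entries are preserved. Standardization is computed across all genes of
#' one population that pass the filters.
#'
#' @param d numeric vector of per-gene D values.
#' @return z-scored vector of the same length.
#' @export
standardize_d <- function(d) {
  ok <- is.finite(d)
  if (sum(ok) < 2L) stop("standardize_d: need >= 2 finite values")
  s <- sd(d[ok])
  if (s == 0) stop("standardize_d: zero variance")
  out <- d
  out[ok] <- (d[ok] - mean(d[ok])) / s
  out
}

#' log10 ratio of non-synonymous to synonymous diversity
#'
#' @param pi_n,pi_s per-site diversity for NS and SYN sites (>= 0).
#' @return `log10(pi_n / pi_s)`; `NaN` when either input is 0 (genes with
#'   an undefined ratio are excluded from models using this covariate).
#' @export
pi_ratio <- function(pi_n, pi_s) {
  if (any(c(pi_n, pi_s) < 0, na.rm = TRUE)) stop("pi_ratio: negative input")
  out <- ifelse(pi_n > 0 & pi_s > 0, log10(pi_n / pi_s), NaN)
  out[is.na(pi_n) | is.na(pi_s)] <- NaN
  out
}

#' Per-gene SFS statistics for one population
#'
#' Aggregates a filtered site table (one pool) into per-gene statistics:
#' segregating NS sites, Tajima's estimators and D on non-synonymous sites,
#' per-site diversity for NS and SYN classes, their log10 ratio, and the
#' across-gene standardized D.
#'
#' @param sites output of [filter_sites()] for one pool.
#' @param population label stored in the output.
#' @param min_snps minimum segregating NS sites for a finite D.
#' @return data.frame with one row per gene: `gene_id`, `population`, `S`,
#'   `theta_pi`, `theta_w`, `D_ns`, `D_ns_std`, `pi_n`, `pi_s`,
#'   `ratio_log10`, `n_sites_ns`, `n_sites_syn`.
#' @export
gene_sfs_stats <- function(sites, population = "pop", min_snps = 3L) {
  dt <- data.table::as.data.table(sites)
  class_stats <- function(f, n) {
    if (length(f) == 0L) return(list(pi = NA_real_, n_sites = 0L))
    ne <- stats::median(n)
    list(pi = sum(2 * f * (1 - f)) * ne / (ne - 1) / length(f),
         n_sites = length(f))
  }
  per_gene <- dt[, {
    ns <- class == "NS"
    sy <- class == "SYN"
    ne_ns <- if (any(ns)) stats::median(n_eff[ns]) else NA_real_
    th <- theta_estimates(freq_hat[ns], max(ne_ns, 2, na.rm = TRUE))
    d <- if (any(ns) && ne_ns >= 4) {
      tajimas_d(th$S, th$theta_pi, th$theta_w, ne_ns, min_snps = min_snps)
    } else NaN
    cn <- class_stats(freq_hat[ns], n_eff[ns])
    cs <- class_stats(freq_hat[sy], n_eff[sy])
    list(S = th$S, theta_pi = th$theta_pi, theta_w = th$theta_w,
         D_ns = d, pi_n = cn$pi, pi_s = cs$pi,
         n_sites_ns = cn$n_sites, n_sites_syn = cs$n_sites)
  }, by = "gene_id"]
  out <- as.data.frame(per_gene)
  out$ratio_log10 <- pi_ratio(out$pi_n, out$pi_s)
  out$D_ns_std <- if (sum(is.finite(out$D_ns)) >= 2L) {
    standardize_d(out$D_ns)
  } else rep(NaN, nrow(out))
  out$population <- population
  out <- out[order(out$gene_id),
             c("gene_id", "population", "S", "theta_pi", "theta_w", "D_ns",
               "D_ns_std", "pi_n", "pi_s", "ratio_log10", "n_sites_ns",
               "n_sites_syn")]
  rownames(out) <- NULL
  out
}
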