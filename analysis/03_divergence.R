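#!/usr/bin/env Rscript
# Stage 3: per-gene pairwise divergence.
#
# For each population pair: the unbiased pooled F_ST (identity-probability
# estimator, ratio of sums over SNPs) and d_XY over all sites passing the
# depth filters in both pools, with logit / log10 transforms. Also writes
# per-pair mean F_ST with bias-corrected bootstrap CIs.

suppressMessages(library(poolfootprint))

for (ds in c("neutral_independent", "discordant_engineered")) {
  dir <- file.path("results/data", ds)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sync <- read_sync(file.path(dir, "counts.sync"),
                    rep(cfg$n_pool_haploid, cfg$n_pops))
  ann <- read_gene_annotation(file.path(dir, "genes.bed"),
                              file.path(dir, "site_classes.tsv"))
  pairs <- utils::combn(cfg$n_pops, 2, simplify = FALSE)
  div <- do.call(rbind, lapply(pairs, function(ij) {
    divergence_pair(sync, ann$site_classes, ij[1], ij[2],
                    sprintf("pop%d-pop%d", ij[1], ij[2]))
  }))
  write_gene_stats(div, file.path("results",
                                  paste0("divergence_", ds, ".tsv")))
  set.seed(1)
  for (pn in unique(div$pair)) {
    ci <- boot_mean_ci(div$fst[div$pair == pn], B = 2000)
    cat(sprintf("%s %s: mean F_ST %.4f [%.4f, %.4f]\n", ds, pn,
                ci$mean, ci$lower, ci$upper))
  }
}
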