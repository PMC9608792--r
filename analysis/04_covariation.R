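#!/usr/bin/env Rscript
# Stage 4: the inference layer.
#
# Links within-population spectra to between-population divergence:
# interaction models of logit F_ST and log10 d_XY on standardized D,
# repeatability (PCA + one-way ANOVA ICC), binned divergence surfaces,
# imbalance gene sets with enrichment against the ground-truth labels,
# sex-bias bins with permutation tests, and the quasi-Poisson fixation
# model. The discordant dataset is expected to show a negative D1 x D2
# interaction for F_ST, an imbalance set dominated by engineered genes,
# and enrichment of the DISCORDANT label; the neutral dataset is the
# benchmark where those signals should be absent.

suppressMessages(library(poolfootprint))

for (ds in c("neutral_independent", "discordant_engineered")) {
  dir <- file.path("results/data", ds)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sync <- read_sync(file.path(dir, "counts.sync"),
                    rep(cfg$n_pool_haploid, cfg$n_pops))
  ann <- read_gene_annotation(file.path(dir, "genes.bed"),
                              file.path(dir, "site_classes.tsv"))
  run <- run_stats(sync, ann, seed = 20260922L)
  term_map <- read_term_map(file.path(dir, "term_map.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"))

  fit_rows <- do.call(rbind, lapply(names(run$fits), function(pn) {
    do.call(rbind, lapply(names(run$fits[[pn]]), function(fn) {
      f <- run$fits[[pn]][[fn]]
      if (!inherits(f, "linear_fit")) return(NULL)
      cbind(data.frame(pair = pn, model = fn), f$terms,
            r_squared = f$r_squared, n = f$n)
    }))
  }))
  write_gene_stats(fit_rows, file.path("results",
                                       paste0("fits_", ds, ".tsv")))

  pn <- "pop1-pop2"
  tab <- run$pair_tables[[pn]]
  imb <- run$imbalance[[pn]]
  universe <- tab$gene_id[is.finite(tab$D1_std) & is.finite(tab$D2_std) &
                            is.finite(tab$fst)]
  enr <- hypergeom_enrichment(intersect(imb$genes, universe), universe,
                              term_map)
  surf <- bin_surface(tab$D1_std, tab$D2_std, tab$fst, tab$gene_id)
  write_gene_stats(as.data.frame(surf$mean),
                   file.path("results", paste0("surface_fst_", ds, ".tsv")))
  sb <- sexbias_bins(expr, tab, "fst_logit", n_perm = 2000, seed = 4)
  poly <- ns_polymorphism_count(run$gene_stats)
  cls <- read_gene_classes(file.path(dir, "gene_classes.tsv"))
  focal <- poly$gene_id %in% cls$gene_id[cls$label == "DISCORDANT"]
  fx <- if (length(unique(poly$n_pops_polymorphic)) > 1 && any(focal)) {
    m <- match(poly$gene_id, expr$gene_id)
    fixation_glm(poly$n_pops_polymorphic, expr$fpkm[m], focal,
                 form = "quadratic")
  } else NULL

  # overall contribution to differentiation: PC1 of the three pairwise
  # vectors, regressed on gene length and GC content
  shared <- Reduce(intersect, lapply(run$pair_stats, function(x) x$gene_id))
  m_fst <- sapply(run$pair_stats, function(x) {
    x$fst_logit[match(shared, x$gene_id)]
  })
  m_dxy <- sapply(run$pair_stats, function(x) {
    x$dxy_log10[match(shared, x$gene_id)]
  })
  keep <- stats::complete.cases(m_fst) & stats::complete.cases(m_dxy)
  r_fst <- repeatability(m_fst[keep, ])
  r_dxy <- repeatability(m_dxy[keep, ])
  gi <- match(shared[keep], ann$genes$gene_id)
  covs <- data.frame(length = ann$genes$length[gi],
                     gc = ann$genes$gc_content[gi])
  # simulated genes share a single length; drop constant covariates
  covs <- covs[, vapply(covs, function(x) sd(x) > 0, TRUE), drop = FALSE]
  pc1_fit <- pc1_regression(r_fst$pc1_scores, covs)
  r_pc1 <- correlate(r_fst$pc1_scores, r_dxy$pc1_scores)

  # focal-class contrast on the engineered pair
  cls_cmp <- {
    focal_genes <- cls$gene_id[cls$label == "DISCORDANT"]
    if (length(focal_genes) >= 5) {
      class_compare(tab$fst_logit, tab$gene_id %in% focal_genes,
                    B = 2000, n_perm = 2000, seed = 3)
    } else NULL
  }

  cat("\n==== ", ds, " ====\n", sep = "")
  print(run)
  cat(sprintf("PC1_FST ~ %s: beta' = %s; R2 = %.3f\n",
              paste(pc1_fit$terms$term[-1], collapse = " + "),
              paste(sprintf("%.3f (p = %.3g)", pc1_fit$terms$beta[-1],
                            pc1_fit$terms$p[-1]), collapse = ", "),
              pc1_fit$r_squared))
  cat(sprintf("correlation of PC1_FST with PC1_dXY across genes: r = %.3f\n",
              r_pc1))
  for (pn in names(run$pair_stats)) {
    ps <- run$pair_stats[[pn]]
    cat(sprintf("  r(F_ST, d_XY) %s: %.3f\n", pn,
                correlate(ps$fst_logit, ps$dxy_log10)))
  }
  if (!is.null(cls_cmp)) {
    cat(sprintf("engineered class vs rest (logit F_ST): t = %.2f, Welch p = %.3g, permutation p = %.4f\n",
                cls_cmp$t, cls_cmp$p, cls_cmp$p_perm))
  }
  cat(sprintf("sex-bias bins: F = %.2f, permutation p = %.4f\n",
              sb$F, sb$p_perm))
  if (!is.null(fx)) {
    cat(sprintf("fixation model dispersion %.2f; class p = %.3g\n",
                fx$dispersion, fx$tests$p[fx$tests$term == "class"]))
  }
  if (nrow(enr)) {
    cat("enrichment of imbalance set:\n")
    print(enr)
  } else cat("no enrichment at p < 0.05\n")
  write_gene_stats(run$pair_means,
                   file.path("results", paste0("pair_means_", ds, ".tsv")))
}
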