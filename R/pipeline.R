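#' Assemble the per-gene modeling table for one population pair
#'
#' Joins the per-population SFS statistics of the two populations with the
#' pair's divergence statistics and the gene covariates into the wide table
#' the models consume.
#'
#' @param stats_x,stats_y outputs of [gene_sfs_stats()] for the two
#'   populations.
#' @param pair_stats output of [divergence_pair()] for the pair.
#' @param genes gene table from [read_gene_annotation()].
#' @return data.frame with one row per gene: `gene_id`, `fst`, `fst_logit`,
#'   `dxy`, `dxy_log10`, `D1_std`, `D2_std`, `D1_raw`, `D2_raw`,
#'   `ratio1_log10`, `ratio2_log10`, `gc_content`, `length`, `n_snps`.
#' @export
assemble_pair_table <- function(stats_x, stats_y, pair_stats, genes) {
  tab <- merge(pair_stats[, c("gene_id", "fst", "fst_logit", "dxy",
                              "dxy_log10", "n_snps")],
               data.frame(gene_id = stats_x$gene_id,
                          D1_std = stats_x$D_ns_std, D1_raw = stats_x$D_ns,
                          ratio1_log10 = stats_x$ratio_log10,
                          stringsAsFactors = FALSE),
               by = "gene_id", all.x = TRUE)
  tab <- merge(tab,
               data.frame(gene_id = stats_y$gene_id,
                          D2_std = stats_y$D_ns_std, D2_raw = stats_y$D_ns,
                          ratio2_log10 = stats_y$ratio_log10,
                          stringsAsFactors = FALSE),
               by = "gene_id", all.x = TRUE)
  tab <- merge(tab, genes[, c("gene_id", "gc_content", "length")],
               by = "gene_id", all.x = TRUE)
  tab[order(tab$gene_id), ]
}

default_filters <- function(filters = NULL) {
  f <- list(min_minor_count = 2L, min_depth = 10L, max_depth = 500L,
            min_snps = 3L)
  for (nm in names(filters)) {
    if (!nm %in% names(f)) stop("unknown filter key: ", nm)
    f[[nm]] <- filters[[nm]]
  }
  f
}

#' Run the full pipeline from allele counts (or a simulation) in memory
#'
#' Computes, for every population and pair: per-gene SFS statistics,
#' divergence statistics, the assembled pair tables, the interaction
#' models (models 1 and 2) with the interaction effect size, imbalance
#' gene sets, repeatability of logit F_ST and log10 d_XY across pairs, and
#' pair means with bootstrap CIs.
#'
#' @param sync a `sync_counts` object.
#' @param annotation list with `genes` and `site_classes` (as returned by
#'   [read_gene_annotation()] or [sim_annotation()]).
#' @param pop_names names for the pools (defaults `pop1`, `pop2`, ...).
#' @param filters list overriding the default site filters
#'   (`min_minor_count` 2, depth window `[10, 500]`, `min_snps` 3).
#' @param seed seed for the bootstrap CIs.
#' @param boot_B bootstrap resamples for pair means.
#' @return list of class `footprint_run` with elements `gene_stats` (one
#'   data.frame per population), `pair_stats`, `pair_tables`, `fits`
#'   (per pair: models 1 and 2 for both responses, plus interaction f2),
#'   `imbalance`, `pair_means`, `repeatability_fst`, `repeatability_dxy`,
#'   `pairs`, `filters`.
#' @export
run_stats <- function(sync, annotation, pop_names = NULL, filters = NULL,
                      seed = 1L, boot_B = 2000L) {
  f <- default_filters(filters)
  n_pools <- length(sync$counts)
  pop_names <- pop_names %||% paste0("pop", seq_len(n_pools))
  stopifnot(length(pop_names) == n_pools)

  gene_stats <- lapply(seq_len(n_pools), function(i) {
    sites <- filter_sites(sync, annotation$site_classes, i,
                          f$min_minor_count, f$min_depth, f$max_depth)
    gene_sfs_stats(sites, pop_names[i], min_snps = f$min_snps)
  })
  names(gene_stats) <- pop_names

  pairs <- list()
  for (i in seq_len(n_pools - 1L)) {
    for (j in (i + 1L):n_pools) {
      pairs[[paste0(pop_names[i], "-", pop_names[j])]] <- c(i, j)
    }
  }
  pair_stats <- lapply(names(pairs), function(pn) {
    ij <- pairs[[pn]]
    divergence_pair(sync, annotation$site_classes, ij[1L], ij[2L], pn,
                    f$min_minor_count, f$min_depth, f$max_depth)
  })
  names(pair_stats) <- names(pairs)

  pair_tables <- lapply(names(pairs), function(pn) {
    ij <- pairs[[pn]]
    assemble_pair_table(gene_stats[[ij[1L]]], gene_stats[[ij[2L]]],
                        pair_stats[[pn]], annotation$genes)
  })
  names(pair_tables) <- names(pairs)

  fits <- lapply(pair_tables, function(tab) {
    m1 <- fit_fst_model(tab, model = 1L)
    m1_red <- fit_fst_model(tab, model = 1L, include_interaction = FALSE)
    d1 <- fit_dxy_model(tab, model = 1L)
    res <- list(fst_model1 = m1, dxy_model1 = d1,
                fst_interaction_f2 = cohens_f2(m1, m1_red))
    m2 <- try(fit_fst_model(tab, model = 2L), silent = TRUE)
    if (!inherits(m2, "try-error")) res$fst_model2 <- m2
    d2 <- try(fit_dxy_model(tab, model = 2L), silent = TRUE)
    if (!inherits(d2, "try-error")) res$dxy_model2 <- d2
    res
  })

  imbalance <- lapply(pair_tables, select_imbalance)

  set.seed(child_seed(seed, 11L))
  pair_means <- do.call(rbind, lapply(names(pairs), function(pn) {
    ci <- boot_mean_ci(pair_stats[[pn]]$fst, B = boot_B)
    data.frame(pair = pn, mean_fst = ci$mean, fst_lower = ci$lower,
               fst_upper = ci$upper,
               mean_dxy = mean(pair_stats[[pn]]$dxy, na.rm = TRUE),
               n_genes = sum(is.finite(pair_stats[[pn]]$fst)),
               stringsAsFactors = FALSE)
  }))

  rep_fst <- rep_dxy <- NULL
  if (length(pairs) >= 2L) {
    shared <- Reduce(intersect, lapply(pair_stats, function(x) x$gene_id))
    fst_m <- sapply(pair_stats, function(x) {
      x$fst_logit[match(shared, x$gene_id)]
    })
    dxy_m <- sapply(pair_stats, function(x) {
      x$dxy_log10[match(shared, x$gene_id)]
    })
    rep_fst <- try(repeatability(fst_m), silent = TRUE)
    rep_dxy <- try(repeatability(dxy_m), silent = TRUE)
    if (inherits(rep_fst, "try-error")) rep_fst <- NULL
    if (inherits(rep_dxy, "try-error")) rep_dxy <- NULL
  }

  out <- list(gene_stats = gene_stats, pair_stats = pair_stats,
              pair_tables = pair_tables, fits = fits,
              imbalance = imbalance, pair_means = pair_means,
              repeatability_fst = rep_fst, repeatability_dxy = rep_dxy,
              pairs = pairs, filters = f, pop_names = pop_names)
  class(out) <- "footprint_run"
  out
}

#' Number of populations segregating non-synonymous variation, per gene
#'
#' @param gene_stats list of per-population tables from [gene_sfs_stats()].
#' @return data.frame `gene_id`, `n_pops_polymorphic` (0..k).
#' @export
ns_polymorphism_count <- function(gene_stats) {
  ids <- sort(unique(unlist(lapply(gene_stats, function(x) x$gene_id))))
  cnt <- rep(0L, length(ids))
  for (st in gene_stats) {
    i <- match(st$gene_id, ids)
    cnt[i] <- cnt[i] + as.integer(st$S > 0L)
  }
  data.frame(gene_id = ids, n_pops_polymorphic = cnt,
             stringsAsFactors = FALSE)
}

validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  missing <- character()
  if (is.null(config$seed)) missing <- c(missing, "seed")
  has_scenario <- !is.null(config$scenario)
  if (!has_scenario) {
    for (key in c("sync", "bed", "site_classes")) {
      if (is.null(config$paths[[key]])) {
        missing <- c(missing, paste0("paths.", key))
      }
    }
    if (is.null(config$pool_sizes)) missing <- c(missing, "pool_sizes")
  }
  if (length(missing)) {
    stop("config schema violation; missing keys: ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(names(config),
                 c("seed", "scenario", "paths", "pool_sizes", "filters",
                   "pop_names", "boot_B"))
  if (length(bad)) {
    stop("config schema violation; unknown keys: ",
         paste(bad, collapse = ", "))
  }
  config
}

#' Run the whole pipeline from a config and write all outputs
#'
#' Stages run in dependency order (simulate if a `scenario` section is
#' present, otherwise read the configured input paths; then per-population
#' statistics, per-pair divergence, covariation models) and every table is
#' written as TSV together with a JSON run manifest (config snapshot,
#' seeds, input hashes, row counts) and a plain-text report. A failed
#' stage aborts with the stage named.
#'
#' @param config path to a YAML config or an equivalent list. Keys:
#'   `seed`; either `scenario` (arguments to [scenario_config()]) or
#'   `paths` (`sync`, `bed`, `site_classes`) plus `pool_sizes`; optional
#'   `filters`, `pop_names`, `boot_B`.
#' @param outdir output directory.
#' @return the `footprint_run`, invisibly; files under `outdir`.
#' @export
run_all <- function(config, outdir) {
  config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  inputs <- stage("input", {
    if (!is.null(config$scenario)) {
      cfg <- do.call(scenario_config,
                     c(config$scenario, list(seed = config$seed)))
      paths <- emit_dataset(cfg, file.path(outdir, "data"))
      list(sync_path = paths$sync, bed = paths$bed,
           site_classes = paths$site_classes,
           pool_sizes = rep(cfg$n_pool_haploid, cfg$n_pops),
           gene_classes = paths$gene_classes, term_map = paths$term_map,
           expression = paths$expression)
    } else {
      list(sync_path = config$paths$sync, bed = config$paths$bed,
           site_classes = config$paths$site_classes,
           pool_sizes = config$pool_sizes,
           gene_classes = config$paths$gene_classes,
           term_map = config$paths$term_map,
           expression = config$paths$expression)
    }
  })
  sync <- stage("read_sync", read_sync(inputs$sync_path, inputs$pool_sizes))
  annotation <- stage("read_annotation",
                      read_gene_annotation(inputs$bed, inputs$site_classes))
  run <- stage("stats", run_stats(sync, annotation,
                                  pop_names = config$pop_names,
                                  filters = config$filters,
                                  seed = config$seed,
                                  boot_B = config$boot_B %||% 2000L))

  enrichment <- NULL
  if (!is.null(inputs$term_map) && file.exists(inputs$term_map)) {
    enrichment <- stage("enrichment", {
      term_map <- read_term_map(inputs$term_map)
      lapply(names(run$imbalance), function(pn) {
        tab <- run$pair_tables[[pn]]
        universe <- tab$gene_id[is.finite(tab$D1_std) &
                                  is.finite(tab$D2_std) &
                                  is.finite(tab$fst)]
        set <- intersect(run$imbalance[[pn]]$genes, universe)
        hypergeom_enrichment(set, universe, term_map)
      })
    })
    names(enrichment) <- names(run$imbalance)
    run$enrichment <- enrichment
  }

  stage("write", {
    write_gene_stats(do.call(rbind, run$gene_stats),
                     file.path(outdir, "gene_stats.tsv"))
    write_gene_stats(do.call(rbind, run$pair_stats),
                     file.path(outdir, "divergence.tsv"))
    fit_rows <- do.call(rbind, lapply(names(run$fits), function(pn) {
      do.call(rbind, lapply(names(run$fits[[pn]]), function(fn) {
        f <- run$fits[[pn]][[fn]]
        if (!inherits(f, "linear_fit")) return(NULL)
        cbind(data.frame(pair = pn, model = fn, stringsAsFactors = FALSE),
              f$terms, r_squared = f$r_squared, n = f$n)
      }))
    }))
    write_gene_stats(fit_rows, file.path(outdir, "fits.tsv"))
    write_gene_stats(run$pair_means, file.path(outdir, "pair_means.tsv"))
    imb <- do.call(rbind, lapply(names(run$imbalance), function(pn) {
      s <- run$imbalance[[pn]]
      if (s$n == 0L) return(NULL)
      data.frame(pair = pn, gene_id = s$genes, stringsAsFactors = FALSE)
    }))
    if (is.null(imb)) {
      imb <- data.frame(pair = character(), gene_id = character())
    }
    write_gene_stats(imb, file.path(outdir, "imbalance.tsv"))
    if (!is.null(enrichment)) {
      enr <- do.call(rbind, lapply(names(enrichment), function(pn) {
        if (nrow(enrichment[[pn]]) == 0L) return(NULL)
        cbind(data.frame(pair = pn, stringsAsFactors = FALSE),
              enrichment[[pn]])
      }))
      if (is.null(enr)) {
        enr <- data.frame(pair = character(), term_id = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric())
      }
      write_gene_stats(enr, file.path(outdir, "enrichment.tsv"))
    }
    rep_row <- function(r, label) {
      if (is.null(r)) return(NULL)
      data.frame(response = label,
                 pc1_variance_fraction = r$pc1_variance_fraction,
                 icc_R = r$icc_R, F = r$F, df1 = r$df[1L], df2 = r$df[2L],
                 p = r$p, n_genes = r$n_genes, stringsAsFactors = FALSE)
    }
    reps <- rbind(rep_row(run$repeatability_fst, "fst_logit"),
                  rep_row(run$repeatability_dxy, "dxy_log10"))
    if (!is.null(reps)) {
      write_gene_stats(reps, file.path(outdir, "repeatability.tsv"))
    }
  })

  stage("manifest", {
    input_files <- c(sync = inputs$sync_path, bed = inputs$bed,
                     site_classes = inputs$site_classes)
    manifest <- list(
      package_version = as.character(utils::packageVersion("poolfootprint")),
      seed = config$seed,
      config = config,
      input_md5 = as.list(tools::md5sum(input_files)),
      rows = list(sync_sites = nrow(sync$sites),
                  genes = nrow(annotation$genes),
                  gene_stats = sum(vapply(run$gene_stats, nrow, 1L)),
                  pairs = length(run$pairs)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  writeLines(report_text(run), file.path(outdir, "report.txt"))
  invisible(run)
}

#' Plain-text summary of a pipeline run
#'
#' @param run a `footprint_run` from [run_stats()] / [run_all()].
#' @return character vector of report lines.
#' @export
report_text <- function(run) {
  lines <- c("poolfootprint run report", "========================", "")
  lines <- c(lines, "Mean F_ST per pair (bias-corrected bootstrap 95% CI):")
  for (i in seq_len(nrow(run$pair_means))) {
    r <- run$pair_means[i, ]
    lines <- c(lines, sprintf("  %s: %.4f [%.4f, %.4f] over %d genes",
                              r$pair, r$mean_fst, r$fst_lower, r$fst_upper,
                              r$n_genes))
  }
  if (!is.null(run$repeatability_fst)) {
    r <- run$repeatability_fst
    lines <- c(lines, "", sprintf(
      "Repeatability of logit F_ST: ICC R = %.3f (F[%d,%d] = %.2f, p = %.3g); PC1 = %.1f%%",
      r$icc_R, r$df[1L], r$df[2L], r$F, r$p, 100 * r$pc1_variance_fraction))
  }
  if (!is.null(run$repeatability_dxy)) {
    r <- run$repeatability_dxy
    lines <- c(lines, sprintf(
      "Repeatability of log10 d_XY: ICC R = %.3f (F[%d,%d] = %.2f, p = %.3g); PC1 = %.1f%%",
      r$icc_R, r$df[1L], r$df[2L], r$F, r$p, 100 * r$pc1_variance_fraction))
  }
  lines <- c(lines, "", "Interaction models (logit F_ST ~ D1 * D2):")
  for (pn in names(run$fits)) {
    f <- run$fits[[pn]]$fst_model1
    ix <- f$terms[f$terms$term == "D1xD2", ]
    lines <- c(lines, sprintf(
      "  %s: beta(D1xD2) = %.3f (t = %.2f, p = %.3g), R2 = %.3f, f2 = %.4f, n = %d",
      pn, ix$beta, ix$t, ix$p, f$r_squared,
      run$fits[[pn]]$fst_interaction_f2, f$n))
  }
  lines <- c(lines, "", "Imbalance gene sets (|dD_std| > 2.5 & F_ST > 0.3):")
  for (pn in names(run$imbalance)) {
    lines <- c(lines, sprintf("  %s: %d of %d genes", pn,
                              run$imbalance[[pn]]$n,
                              run$imbalance[[pn]]$n_candidates))
  }
  if (!is.null(run$enrichment)) {
    lines <- c(lines, "", "Top enrichment rows:")
    for (pn in names(run$enrichment)) {
      e <- run$enrichment[[pn]]
      if (nrow(e) == 0L) {
        lines <- c(lines, sprintf("  %s: none at p < 0.05", pn))
      } else {
        top <- e[1L, ]
        lines <- c(lines, sprintf("  %s: %s (k=%d/%d, K=%d/%d, p = %.3g)",
                                  pn, top$term_id, top$k, top$n, top$K,
                                  top$N, top$p))
      }
    }
  }
  lines
}

#' @export
print.footprint_run <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}
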