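#' Configuration for the forward simulator
#'
#' Collects the parameters of the multi-gene Wright-Fisher simulator and
#' pool-sequencing emulator with validated defaults. Defaults emulate the
#' study conditions the pipeline is meant for: three populations split from
#' a common ancestor, pools of 200 diploid males (400 haploid genomes)
#' sequenced to a mean depth of 125x, synonymous diversity near 0.022 and a
#' coding SNP density of roughly 6 per kb (set via `mu = 1.1e-5` at
#' `N = 500`, i.e. 4N*mu = 0.022, with about 120 mutable loci per 2 kb
#' gene).
#'
#' Scenarios:
#' * `NEUTRAL_INDEPENDENT`: all loci neutral, populations drift apart.
#' * `STABILIZING_SHARED`: each gene's non-synonymous loci contribute
#'   additively to a trait under Gaussian stabilizing selection with the
#'   same optimum in every population.
#' * `STABILIZING_SHIFTED`: as above but optima differ between populations
#'   after the split (`theta_opt`).
#' * `DISCORDANT_ENGINEERED`: a labeled fraction of genes receives, after
#'   the split, discordant selection at the gene's intermediate-frequency
#'   non-synonymous loci: directional selection in one population (the
#'   gene's "sweep population", randomly population 1 or 2, driving the
#'   major allele upward in an incomplete sweep that skews the spectrum
#'   toward rare variants) and heterozygote advantage at the same loci in
#'   the other (holding and accumulating intermediate-frequency
#'   variants). This is the deterministic generator of the imbalance
#'   footprint: rare-variant excess in one population, balanced
#'   frequencies in the other, high F_ST between them, in either
#'   direction across genes.
#'
#' @param scenario one of the four scenario names.
#' @param N diploid population size.
#' @param n_pops number of populations split from the ancestor.
#' @param G_split generations from split to sampling.
#' @param L_genes number of genes.
#' @param n_ns,n_syn non-synonymous and synonymous mutable loci per gene.
#' @param gene_length gene length in bases (non-mutable remainder is
#'   emitted as monomorphic "OTHER" sites for d_XY denominators).
#' @param mu per-site per-generation reversible mutation rate.
#' @param omega stabilizing-selection width (trait SD units; `Inf` turns
#'   selection off).
#' @param theta_opt per-population trait optima (recycled to `n_pops`).
#' @param alpha_rate rate of the exponential effect-size distribution for
#'   non-synonymous loci (signs random).
#' @param discordant_frac fraction of genes engineered in the discordant
#'   scenario.
#' @param s_dir,s_het selection coefficients of the directional and
#'   heterozygote-advantage regimes of the discordant scenario.
#' @param sel_min_maf minimum split-time minor-allele frequency for a
#'   locus to be targeted by discordant selection.
#' @param depth_mean mean Poisson sequencing depth per site per pool.
#' @param n_pool_haploid haploid pool size (chromosomes pooled).
#' @param burn_in generations of ancestral burn-in (frequencies are
#'   initialized at the reversible-mutation stationary distribution
#'   Beta(4N mu, 4N mu), so the burn-in only needs to settle the selected
#'   scenarios; about N generations suffices).
#' @param seed integer seed governing every random draw.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("NEUTRAL_INDEPENDENT",
                                         "STABILIZING_SHARED",
                                         "STABILIZING_SHIFTED",
                                         "DISCORDANT_ENGINEERED"),
                            N = 500L, n_pops = 3L, G_split = 300L,
                            L_genes = 300L, n_ns = 80L, n_syn = 40L,
                            gene_length = 2000L, mu = 1.1e-5,
                            omega = Inf, theta_opt = 0,
                            alpha_rate = 1, discordant_frac = 0.25,
                            s_dir = 0.01, s_het = 0.1, sel_min_maf = 0.05,
                            depth_mean = 125, n_pool_haploid = 400L,
                            burn_in = 500L, seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- list(scenario = scenario, N = as.integer(N),
              n_pops = as.integer(n_pops), G_split = as.integer(G_split),
              L_genes = as.integer(L_genes), n_ns = as.integer(n_ns),
              n_syn = as.integer(n_syn), gene_length = as.integer(gene_length),
              mu = mu, omega = omega,
              theta_opt = rep_len(theta_opt, n_pops),
              alpha_rate = alpha_rate, discordant_frac = discordant_frac,
              s_dir = s_dir, s_het = s_het, sel_min_maf = sel_min_maf,
              depth_mean = depth_mean,
              n_pool_haploid = as.integer(n_pool_haploid),
              burn_in = as.integer(burn_in), seed = as.integer(seed))
  stopifnot(cfg$N >= 2L, cfg$mu > 0, cfg$omega > 0, cfg$depth_mean > 0,
            cfg$n_pops >= 2L, cfg$L_genes >= 1L, cfg$n_ns >= 1L,
            cfg$n_syn >= 0L, cfg$gene_length >= cfg$n_ns + cfg$n_syn,
            cfg$discordant_frac >= 0, cfg$discordant_frac <= 1,
            cfg$n_pool_haploid >= 2L)
  class(cfg) <- "scenario_config"
  cfg
}

# draw diploid individuals (two allele matrices) from locus frequencies
sample_individuals <- function(p, N) {
  L <- length(p)
  list(A1 = matrix(rbinom(N * L, 1L, rep(p, each = N)), N, L),
       A2 = matrix(rbinom(N * L, 1L, rep(p, each = N)), N, L))
}

ind_freqs <- function(ind) {
  colMeans(ind$A1 + ind$A2) / 2
}

# evolve one gene's NS loci under an individual-based regime, from and to
# frequencies (populations are re-founded from frequencies at each epoch
# boundary, equivalent to one extra generation of binomial sampling)
evolve_gene_selected <- function(p, cfg, mode, sel_idx, fav, alpha, opt,
                                 generations) {
  ind <- sample_individuals(p, cfg$N)
  res <- wf_gene_evolve(ind$A1, ind$A2, mode, as.integer(sel_idx - 1L),
                        as.integer(fav), as.numeric(alpha), opt,
                        if (is.finite(cfg$omega)) cfg$omega else 1,
                        if (mode == 2L) cfg$s_dir else cfg$s_het,
                        cfg$mu, generations)
  colMeans(res$A1 + res$A2) / 2
}

#' Simulate multi-gene population divergence
#'
#' Forward Wright-Fisher simulation of `L_genes` unlinked genes in a
#' common ancestor, followed by an `n_pops`-way split and `G_split`
#' generations of independent evolution under the configured scenario.
#' Neutral unlinked loci are advanced by the exact allele-frequency
#' binomial form of the diploid process; genes under selection use a
#' diploid individual-based kernel (selection acts on whole individuals).
#' All randomness flows from `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `sim_result`: `freqs` (list per population of
#'   `L_genes x (n_ns + n_syn)` true allele-frequency matrices), `anc`
#'   (ancestral frequencies at the split), `truth` (per-gene data.frame:
#'   `gene_id`, `scenario_class`, `n_selected`, plus true per-pair
#'   F_ST/d_XY), `alpha`, `selected` (list of selected locus indices),
#'   and `cfg`.
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  L <- cfg$n_ns + cfg$n_syn
  G <- cfg$L_genes
  beta_par <- 4 * cfg$N * cfg$mu
  p0 <- matrix(rbeta(G * L, beta_par, beta_par), G, L)
  p0[!is.finite(p0)] <- 0  # rbeta underflow at tiny shape
  alpha <- matrix(sample(c(-1, 1), G * cfg$n_ns, replace = TRUE) *
                    rexp(G * cfg$n_ns, rate = cfg$alpha_rate), G, cfg$n_ns)
  ns_idx <- seq_len(cfg$n_ns)

  stabilizing <- cfg$scenario %in% c("STABILIZING_SHARED",
                                     "STABILIZING_SHIFTED")
  # ancestral burn-in
  if (stabilizing) {
    if (!is.finite(cfg$omega)) {
      stop("stabilizing scenarios need a finite omega")
    }
    anc <- p0
    for (g in seq_len(G)) {
      anc[g, ] <- {
        ind <- sample_individuals(p0[g, ], cfg$N)
        res <- wf_gene_evolve(ind$A1, ind$A2, 1L,
                              as.integer(ns_idx - 1L), integer(0),
                              as.numeric(alpha[g, ]), 0, cfg$omega, 0,
                              cfg$mu, cfg$burn_in)
        colMeans(res$A1 + res$A2) / 2
      }
    }
  } else {
    anc <- matrix(wf_neutral_freq(as.numeric(p0), cfg$N, cfg$mu,
                                  cfg$burn_in), G, L)
  }

  discordant <- rep(FALSE, G)
  selected <- vector("list", G)
  sweep_pop <- rep(NA_integer_, G)
  if (cfg$scenario == "DISCORDANT_ENGINEERED") {
    discordant[sample.int(G, round(cfg$discordant_frac * G))] <- TRUE
    # the imbalance runs in either direction: for half the engineered
    # genes population 1 is the sweep population, for the other half
    # population 2 is
    sweep_pop[discordant] <- sample(rep_len(1:2, sum(discordant)))
    for (g in which(discordant)) {
      maf <- pmin(anc[g, ns_idx], 1 - anc[g, ns_idx])
      selected[[g]] <- ns_idx[maf > cfg$sel_min_maf]
    }
  }

  pops <- vector("list", cfg$n_pops)
  for (pop in seq_len(cfg$n_pops)) {
    pf <- anc
    if (cfg$scenario %in% c("NEUTRAL_INDEPENDENT", "DISCORDANT_ENGINEERED")) {
      # unlinked loci without selection in this population evolve by the
      # exact binomial frequency process; only the engineered loci need
      # the individual-based kernel
      engineered <- cfg$scenario == "DISCORDANT_ENGINEERED" && pop <= 2L
      neutral_mask <- matrix(TRUE, G, L)
      if (engineered) {
        for (g in which(discordant)) {
          sel <- selected[[g]]
          if (length(sel)) neutral_mask[g, sel] <- FALSE
        }
      }
      pf[neutral_mask] <- wf_neutral_freq(as.numeric(anc[neutral_mask]),
                                          cfg$N, cfg$mu, cfg$G_split)
      if (engineered) {
        for (g in which(discordant)) {
          sel <- selected[[g]]
          if (length(sel) == 0L) next
          # directional (incomplete sweep) in the gene's sweep
          # population, heterozygote advantage in the other
          sel_mode <- if (sweep_pop[g] == pop) 2L else 3L
          fav <- as.integer(anc[g, sel] >= 0.5)  # drive the major allele up
          pf[g, sel] <- evolve_gene_selected(anc[g, sel], cfg, sel_mode,
                                             seq_along(sel), fav,
                                             numeric(0), 0, cfg$G_split)
        }
      }
    } else {
      # stabilizing scenarios: every gene individual-based on its NS loci;
      # SYN loci are neutral and unlinked, frequency-based
      syn_idx <- setdiff(seq_len(L), ns_idx)
      if (length(syn_idx)) {
        pf[, syn_idx] <- matrix(wf_neutral_freq(as.numeric(anc[, syn_idx]),
                                                cfg$N, cfg$mu, cfg$G_split),
                                G, length(syn_idx))
      }
      for (g in seq_len(G)) {
        pf[g, ns_idx] <- evolve_gene_selected(anc[g, ns_idx], cfg, 1L,
                                              ns_idx, integer(0),
                                              alpha[g, ],
                                              cfg$theta_opt[pop],
                                              cfg$G_split)
      }
    }
    pops[[pop]] <- pf
  }

  gene_ids <- sprintf("g%04d", seq_len(G))
  truth <- data.frame(gene_id = gene_ids,
                      scenario_class = ifelse(discordant, "DISCORDANT",
                                              cfg$scenario),
                      n_selected = vapply(selected, length, 1L),
                      sweep_pop = sweep_pop,
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_pops - 1L)) {
    for (j in (i + 1L):cfg$n_pops) {
      px <- pops[[i]]; py <- pops[[j]]
      hb <- px * (1 - py) + py * (1 - px)
      hw <- (2 * px * (1 - px) + 2 * py * (1 - py)) / 2
      truth[[sprintf("fst_true_%d_%d", i, j)]] <-
        rowSums(hb - hw) / pmax(rowSums(hb), .Machine$double.eps)
      truth[[sprintf("dxy_true_%d_%d", i, j)]] <-
        rowSums(hb) / cfg$gene_length
    }
  }
  out <- list(freqs = pops, anc = anc, truth = truth, alpha = alpha,
              selected = selected, cfg = cfg)
  class(out) <- "sim_result"
  out
}

#' Emulate pool sequencing of simulated populations
#'
#' Two-stage sampling per site and pool: (1) `n_pool_haploid` chromosomes
#' are drawn binomially from the population allele frequency, (2) a
#' Poisson-distributed number of reads is drawn binomially from the pool
#' frequency. Mutable loci occupy positions `1..(n_ns+n_syn)` of each
#' gene's contig (NS first); the remaining positions are emitted as
#' monomorphic reference sites so absolute-divergence denominators count
#' every site. Reference allele is A, alternative C.
#'
#' @param sim a `sim_result` from [simulate_populations()].
#' @param seed seed for the sequencing noise (independent of the
#'   evolutionary seed; defaults to a child of `cfg$seed`).
#' @return a `sync_counts` object with one pool per population.
#' @export
pool_sequence <- function(sim, seed = child_seed(sim$cfg$seed, 1L)) {
  cfg <- sim$cfg
  set.seed(seed)
  G <- cfg$L_genes
  L <- cfg$n_ns + cfg$n_syn
  n_fill <- cfg$gene_length - L
  gene_ids <- sprintf("g%04d", seq_len(G))
  contig <- rep(gene_ids, each = cfg$gene_length)
  pos <- rep.int(seq_len(cfg$gene_length), G)
  n_sites <- G * cfg$gene_length
  var_rows <- which(pos <= L)  # mutable loci rows in site order

  counts <- vector("list", cfg$n_pops)
  for (pop in seq_len(cfg$n_pops)) {
    depth <- rpois(n_sites, cfg$depth_mean)
    alt <- integer(n_sites)
    p <- as.numeric(t(sim$freqs[[pop]]))  # site order within gene
    nv <- length(var_rows)
    y <- rbinom(nv, cfg$n_pool_haploid, p) / cfg$n_pool_haploid
    alt[var_rows] <- rbinom(nv, depth[var_rows], y)
    m <- matrix(0L, n_sites, 6L, dimnames = list(NULL, BASES6))
    m[, "A"] <- as.integer(depth - alt)
    m[, "C"] <- as.integer(alt)
    counts[[pop]] <- m
  }
  sync <- list(sites = data.frame(contig = contig, pos = pos,
                                  ref_base = "A", stringsAsFactors = FALSE),
               counts = counts,
               pool_sizes = rep(cfg$n_pool_haploid, cfg$n_pops))
  class(sync) <- "sync_counts"
  sync
}

#' Build the annotation tables matching a simulated dataset
#'
#' @param cfg a [scenario_config()].
#' @param seed seed for the annotation draws (GC content, expression).
#' @return list with `genes`, `site_classes`, `gene_classes`, `term_map`,
#'   `expression` in the same shapes the readers produce.
#' @export
sim_annotation <- function(cfg, seed = child_seed(cfg$seed, 2L)) {
  set.seed(seed)
  G <- cfg$L_genes
  L <- cfg$n_ns + cfg$n_syn
  gene_ids <- sprintf("g%04d", seq_len(G))
  genes <- data.frame(gene_id = gene_ids, contig = gene_ids, start = 0L,
                      end = cfg$gene_length, length = cfg$gene_length,
                      gc_content = round(runif(G, 0.3, 0.6), 4),
                      stringsAsFactors = FALSE)
  site_classes <- data.frame(
    contig = rep(gene_ids, each = cfg$gene_length),
    pos = rep.int(seq_len(cfg$gene_length), G),
    gene_id = rep(gene_ids, each = cfg$gene_length),
    class = rep.int(c(rep("NS", cfg$n_ns), rep("SYN", cfg$n_syn),
                      rep("OTHER", cfg$gene_length - L)), G),
    stringsAsFactors = FALSE)
  fpkm <- rlnorm(G, meanlog = 3, sdlog = 1.2)
  l2fc <- rnorm(G, 0, 1.5)
  expression <- data.frame(gene_id = gene_ids, fpkm = fpkm,
                           log2fc_sex = l2fc,
                           bias_class = ifelse(l2fc > 0.5, "FBG",
                                               ifelse(l2fc < -0.5, "MBG",
                                                      "UNBIASED")),
                           stringsAsFactors = FALSE)
  list(genes = genes, site_classes = site_classes, expression = expression)
}

#' Write a complete simulated dataset to disk
#'
#' Runs [simulate_populations()] and [pool_sequence()], then writes every
#' file the pipeline readers consume: `counts.sync`, `genes.bed` (gene id
#' in column 4, GC content in column 5), `site_classes.tsv`,
#' `gene_classes.tsv` and `term_map.tsv` (ground-truth scenario labels plus
#' decoy terms), `expression.tsv`, `truth.tsv`, and `config.yaml`.
#'
#' @param cfg a [scenario_config()].
#' @param outdir output directory (created if missing).
#' @return named list of file paths, invisibly; the `sim_result` is
#'   attached as attribute `sim`.
#' @export
emit_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_populations(cfg)
  sync <- pool_sequence(sim)
  ann <- sim_annotation(cfg)

  paths <- list(sync = file.path(outdir, "counts.sync"),
                bed = file.path(outdir, "genes.bed"),
                site_classes = file.path(outdir, "site_classes.tsv"),
                gene_classes = file.path(outdir, "gene_classes.tsv"),
                term_map = file.path(outdir, "term_map.tsv"),
                expression = file.path(outdir, "expression.tsv"),
                truth = file.path(outdir, "truth.tsv"),
                config = file.path(outdir, "config.yaml"))
  write_sync(sync, paths$sync)
  bed <- ann$genes[, c("contig", "start", "end", "gene_id", "gc_content")]
  data.table::fwrite(bed, paths$bed, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(ann$site_classes, paths$site_classes, sep = "\t",
                     quote = FALSE)
  gene_classes <- data.frame(gene_id = sim$truth$gene_id,
                             label = sim$truth$scenario_class,
                             stringsAsFactors = FALSE)
  data.table::fwrite(gene_classes, paths$gene_classes, sep = "\t",
                     quote = FALSE)
  set.seed(child_seed(cfg$seed, 3L))
  decoys <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(term_id = sprintf("DECOY%02d", i),
               gene_id = sample(sim$truth$gene_id,
                                max(2L, round(0.1 * cfg$L_genes))),
               stringsAsFactors = FALSE)
  }))
  term_map <- rbind(
    data.frame(term_id = sim$truth$scenario_class,
               gene_id = sim$truth$gene_id, stringsAsFactors = FALSE),
    decoys)
  data.table::fwrite(term_map, paths$term_map, sep = "\t", quote = FALSE)
  data.table::fwrite(ann$expression, paths$expression, sep = "\t",
                     quote = FALSE)
  data.table::fwrite(sim$truth, paths$truth, sep = "\t", quote = FALSE)
  yaml::write_yaml(unclass(cfg), paths$config)
  out <- paths
  attr(out, "sim") <- sim
  invisible(out)
}
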