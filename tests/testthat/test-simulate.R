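test_that("scenario_config validates its invariants", {
  cfg <- scenario_config()
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$n_pool_haploid, 400L)
  expect_equal(cfg$depth_mean, 125)
  expect_error(scenario_config(N = 1), "N")
  expect_error(scenario_config(mu = 0))
  expect_error(scenario_config(gene_length = 10, n_ns = 20, n_syn = 5))
})

test_that("same seed reproduces frequencies bit-identically", {
  cfg <- scenario_config("DISCORDANT_ENGINEERED", L_genes = 12,
                         n_ns = 10, n_syn = 5, gene_length = 40,
                         burn_in = 50, G_split = 40, seed = 5)
  a <- simulate_populations(cfg)
  b <- simulate_populations(cfg)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$truth, b$truth)
  sync_a <- pool_sequence(a)
  sync_b <- pool_sequence(b)
  expect_identical(sync_a$counts, sync_b$counts)
})

test_that("neutral drift variance matches the closed form", {
  # single locus at 0.5, N = 500, t = 100, 500 replicates:
  # Var(p_t) = 0.25 * (1 - (1 - 1/(2N))^t)
  set.seed(9)
  N <- 500; t_gen <- 100
  p_fin <- poolfootprint:::wf_neutral_freq(rep(0.5, 500), N, 0, t_gen)
  expected <- 0.25 * (1 - (1 - 1 / (2 * N))^t_gen)
  expect_lt(abs(var(p_fin) / expected - 1), 0.15)
})

test_that("neutral heterozygosity decays at the Wright-Fisher rate", {
  set.seed(10)
  N <- 500; t_gen <- 200
  n_loci <- 2000
  p0 <- runif(n_loci, 0.2, 0.8)
  p_fin <- poolfootprint:::wf_neutral_freq(p0, N, 0, t_gen)
  h0 <- mean(2 * p0 * (1 - p0))
  ht <- mean(2 * p_fin * (1 - p_fin))
  expect_lt(abs(ht / (h0 * (1 - 1 / (2 * N))^t_gen) - 1), 0.1)
})

test_that("pool sequencing matches the two-stage compound variance", {
  # frequency 0.5, Poisson depth 125, pool 400; Var(p_hat) =
  # Var(y) + E[y(1-y)/c] with y ~ Bin(n,x)/n and c ~ Poisson (c > 0)
  cfg <- scenario_config("NEUTRAL_INDEPENDENT", L_genes = 10, n_ns = 500,
                         n_syn = 500, gene_length = 1000, seed = 3)
  sim <- simulate_populations(cfg)
  sim$freqs[[1]][] <- 0.5
  sync <- pool_sequence(sim, seed = 99)
  m <- sync$counts[[1]]
  depth <- m[, "A"] + m[, "C"]
  keep <- depth > 0
  fr <- m[keep, "C"] / depth[keep]
  x <- 0.5; n <- 400; lam <- 125
  e_inv_c <- sum(1 / (1:400) * dpois(1:400, lam)) / (1 - dpois(0, lam))
  var_expected <- x * (1 - x) / n + x * (1 - x) * (1 - 1 / n) * e_inv_c
  expect_lt(abs(var(fr) / var_expected - 1), 0.1)
})

test_that("frequency 0 yields all-reference counts", {
  cfg <- scenario_config("NEUTRAL_INDEPENDENT", L_genes = 2, n_ns = 5,
                         n_syn = 5, gene_length = 20, seed = 4)
  sim <- simulate_populations(cfg)
  for (pop in 1:3) sim$freqs[[pop]][] <- 0
  sync <- pool_sequence(sim)
  for (pop in 1:3) {
    expect_true(all(sync$counts[[pop]][, "C"] == 0L))
  }
})

test_that("stabilizing selection holds the trait near its optimum", {
  cfg <- scenario_config("STABILIZING_SHARED", L_genes = 6, n_ns = 20,
                         n_syn = 10, gene_length = 60, omega = 1,
                         burn_in = 150, G_split = 100, N = 200, seed = 6)
  sim <- simulate_populations(cfg)
  # a gene whose standing variation cannot reach the optimum stays stuck
  # (mutation-limited), so containment is relative to the post-burn-in
  # state: stabilizing selection must not let the trait mean drift away
  # from the optimum by more than a few omega beyond where it started
  z0 <- abs(rowSums(2 * sim$anc[, 1:20] * sim$alpha) - cfg$theta_opt[1])
  for (pop in 1:3) {
    z <- abs(rowSums(2 * sim$freqs[[pop]][, 1:20] * sim$alpha) -
               cfg$theta_opt[pop])
    expect_true(all(z <= z0 + 2 * cfg$omega))
  }
})

test_that("shifted optima diverge trait means more than shared optima", {
  base <- list(L_genes = 8, n_ns = 16, n_syn = 8, gene_length = 48,
               omega = 1, burn_in = 150, G_split = 150, N = 200, seed = 12)
  shared <- do.call(scenario_config,
                    c(list(scenario = "STABILIZING_SHARED"), base))
  shifted <- do.call(scenario_config,
                     c(list(scenario = "STABILIZING_SHIFTED",
                            theta_opt = c(-2, 0, 2)), base))
  trait_div <- function(sim) {
    zs <- sapply(1:3, function(pop) {
      rowSums(2 * sim$freqs[[pop]][, 1:16] * sim$alpha)
    })
    mean(apply(zs, 1, var))
  }
  expect_gt(trait_div(simulate_populations(shifted)),
            trait_div(simulate_populations(shared)))
})

test_that("discordant genes show the engineered SFS imbalance", {
  cfg <- scenario_config("DISCORDANT_ENGINEERED", L_genes = 100, seed = 31)
  sim <- simulate_populations(cfg)
  sync <- pool_sequence(sim)
  ann <- sim_annotation(cfg)
  st1 <- gene_sfs_stats(filter_sites(sync, ann$site_classes, 1), "pop1")
  st2 <- gene_sfs_stats(filter_sites(sync, ann$site_classes, 2), "pop2")
  disc <- sim$truth$scenario_class == "DISCORDANT"
  sweep1 <- sim$truth$gene_id[disc & sim$truth$sweep_pop == 1L]
  sweep2 <- sim$truth$gene_id[disc & sim$truth$sweep_pop == 2L]
  d_of <- function(st, ids) mean(st$D_ns_std[st$gene_id %in% ids],
                                 na.rm = TRUE)
  # sweep population: rare-variant excess (negative standardized D);
  # balancing population: intermediate-frequency excess (positive)
  expect_lt(d_of(st1, sweep1), 0)
  expect_gt(d_of(st2, sweep1), 0)
  expect_lt(d_of(st2, sweep2), 0)
  expect_gt(d_of(st1, sweep2), 0)
  # neutral genes sit in between
  neut <- sim$truth$gene_id[!disc]
  expect_gt(d_of(st1, neut), d_of(st1, sweep1))
  expect_lt(d_of(st2, neut), d_of(st2, sweep1))
})

test_that("emit_dataset writes a consistent, re-readable bundle", {
  outdir <- file.path(tempdir(), "emit_test")
  cfg <- scenario_config("DISCORDANT_ENGINEERED", L_genes = 25, n_ns = 20,
                         n_syn = 10, gene_length = 100, burn_in = 100,
                         G_split = 80, seed = 8)
  paths <- emit_dataset(cfg, outdir)
  expect_true(all(file.exists(unlist(paths))))
  sync <- read_sync(paths$sync, rep(cfg$n_pool_haploid, 3))
  ann <- read_gene_annotation(paths$bed, paths$site_classes)
  expect_equal(nrow(ann$genes), 25L)
  # every gene in the BED has sites in the sync stream
  expect_true(all(ann$genes$gene_id %in%
                    unique(ann$site_classes$gene_id)))
  expect_setequal(unique(sync$sites$contig), ann$genes$contig)
  # every sync site is classified
  key_sync <- paste(sync$sites$contig, sync$sites$pos)
  key_cls <- paste(ann$site_classes$contig, ann$site_classes$pos)
  expect_true(all(key_sync %in% key_cls))
  classes <- read_gene_classes(paths$gene_classes, ann$genes)
  expect_true(any(classes$label == "DISCORDANT"))
  tm <- read_term_map(paths$term_map)
  expect_true("DISCORDANT" %in% names(tm))
  expr <- read_expression(paths$expression)
  expect_equal(nrow(expr), 25L)
})

test_that("pipeline FST recovers truth FST across genes", {
  cfg <- scenario_config("NEUTRAL_INDEPENDENT", L_genes = 300, seed = 13)
  sim <- simulate_populations(cfg)
  sync <- pool_sequence(sim)
  ann <- sim_annotation(cfg)
  div <- divergence_pair(sync, ann$site_classes, 1, 2)
  m <- match(div$gene_id, sim$truth$gene_id)
  ok <- is.finite(div$fst)
  expect_gt(cor(div$fst[ok], sim$truth$fst_true_1_2[m][ok]), 0.7)
})
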