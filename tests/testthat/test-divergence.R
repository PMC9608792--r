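test_that("dxy_gene matches hand evaluation of the printed formula", {
  # single fixed difference over one site
  expect_equal(dxy_gene(1, 0, 1L), 1)
  # sites {(1,0), (0.5,0.5)} over 10 sites: (1 + 0.5)/10
  expect_equal(dxy_gene(c(1, 0.5), c(0, 0.5), 10L), 0.15)
  # empty window
  expect_true(is.nan(dxy_gene(numeric(0), numeric(0), 0L)))
  expect_error(dxy_gene(c(0.5, 0.5), c(0.5, 0.5), 1L))
})

test_that("dxy is symmetric in populations and allele labels", {
  set.seed(3)
  for (i in 1:20) {
    ns <- sample(2:30, 1)
    ax <- runif(ns); ay <- runif(ns)
    tot <- ns + sample(0:50, 1)
    expect_equal(dxy_gene(ax, ay, tot), dxy_gene(ay, ax, tot))
    # relabeling alleles (A <-> B) per site leaves dxy unchanged
    expect_equal(dxy_gene(ax, ay, tot), dxy_gene(1 - ax, 1 - ay, tot))
  }
})

test_that("fixed differences give near-unit FST", {
  # 100 SNPs fixed for alternative alleles, depth 100, pool 400
  pair <- data.frame(gene_id = "gene1", pos = 1:100,
                     cx1 = 100L, cx2 = 0L, cy1 = 0L, cy2 = 100L,
                     ax = 1, ay = 0, is_snp = TRUE,
                     stringsAsFactors = FALSE)
  res <- fst_gene(pair, n_pool_x = 400, n_pool_y = 400)
  expect_gte(res$fst, 0.95)
  expect_equal(res$q2_hat, 0)
  expect_equal(res$n_snps, 100L)
})

test_that("no SNPs yields NaN with zero-count bookkeeping", {
  pair <- data.frame(gene_id = "gene1", pos = 1:5,
                     cx1 = 50L, cx2 = 0L, cy1 = 50L, cy2 = 0L,
                     ax = 1, ay = 1, is_snp = FALSE,
                     stringsAsFactors = FALSE)
  res <- fst_gene(pair, 400, 400)
  expect_true(is.nan(res$fst))
  expect_equal(res$n_snps, 0L)
})

test_that("identical-frequency pools give mean FST near zero", {
  # Monte-Carlo check of unbiasedness: 50 replicate genes of 200 SNPs,
  # both pools drawn from the same frequencies at depth 100
  set.seed(21)
  fsts <- vapply(1:50, function(r) {
    p <- runif(200, 0.05, 0.95)
    pair <- simulate_pair_counts(p, p, depth = 100, n_pool = 400)
    fst_gene(pair)$fst
  }, 1)
  expect_lt(abs(mean(fsts)), 0.01)
})

test_that("pooled FST converges to the Hudson estimator at deep sampling", {
  set.seed(22)
  p_x <- runif(200, 0.05, 0.95)
  p_y <- pmin(pmax(p_x + rnorm(200, 0, 0.2), 0), 1)
  pair <- simulate_pair_counts(p_x, p_y, depth = 1e4, n_pool = 1e4)
  res <- fst_gene(pair)
  expect_equal(res$fst, oracle_hudson_fst(p_x, p_y), tolerance = 0.01)
  expect_lte(res$q2_hat, 1)
  expect_gt(1 - res$q2_hat, 0)
})

test_that("drift-only divergence tracks the closed-form expectation", {
  # pure drift from a common ancestor: E[FST] = 1 - (1 - 1/(2N))^t;
  # mutation off after the split so drift is the only force
  set.seed(23)
  N <- 500; t_split <- 150
  n_genes <- 300; loci <- 12
  p0 <- matrix(rbeta(n_genes * loci, 0.022, 0.022), n_genes, loci)
  p0[!is.finite(p0)] <- 0
  px <- matrix(poolfootprint:::wf_neutral_freq(as.numeric(p0), N, 0, t_split),
               n_genes, loci)
  py <- matrix(poolfootprint:::wf_neutral_freq(as.numeric(p0), N, 0, t_split),
               n_genes, loci)
  num <- den <- 0
  for (g in seq_len(n_genes)) {
    yx <- rbinom(loci, 400, px[g, ]) / 400
    yy <- rbinom(loci, 400, py[g, ]) / 400
    cx1 <- rbinom(loci, 100, yx); cy1 <- rbinom(loci, 100, yy)
    pair <- data.frame(gene_id = "g", pos = seq_len(loci),
                       cx1 = cx1, cx2 = 100L - cx1,
                       cy1 = cy1, cy2 = 100L - cy1,
                       ax = cx1 / 100, ay = cy1 / 100,
                       is_snp = TRUE, stringsAsFactors = FALSE)
    res <- fst_gene(pair, 400, 400)
    # accumulate the ratio-of-sums across genes via its components
    if (is.finite(res$fst)) {
      num <- num + (res$q1_hat - res$q2_hat) * res$n_snps
      den <- den + (1 - res$q2_hat) * res$n_snps
    }
  }
  expected <- 1 - (1 - 1 / (2 * N))^t_split
  expect_lt(abs(num / den - expected), 0.03)
})

test_that("transform_divergence clamps before transforming", {
  tab <- data.frame(fst = c(0.5, -0.002, 0.9999), dxy = c(0.01, 0, 0.5))
  out <- transform_divergence(tab)
  expect_equal(out$fst_logit[1], 0)
  expect_equal(out$fst_logit[2], log(1e-4 / (1 - 1e-4)))
  expect_equal(out$dxy_log10[1], -2)
  expect_equal(out$dxy_log10[2], -6)
  expect_equal(out$fst[2], -0.002)  # raw value retained
})

test_that("divergence_pair integrates filters, SNP calls and windows", {
  # gene of 6 sites: a fixed difference, a shared polymorphism, a
  # sub-threshold minor (treated monomorphic), a monomorphic site, a
  # low-depth site (dropped), and a triallelic site reduced to two alleles
  cx <- count_matrix(a = c(0, 60, 99, 100, 3, 50),
                     c = c(100, 40, 1, 0, 2, 30),
                     g = c(0, 0, 0, 0, 0, 20))
  cy <- count_matrix(a = c(100, 55, 100, 100, 5, 80),
                     c = c(0, 45, 0, 0, 0, 20),
                     g = 0)
  sync <- make_sync(rep("ctg1", 6), 1:6, list(cx, cy), c(400, 400))
  ann <- one_gene_annotation(6L)
  out <- divergence_pair(sync, ann$site_classes, 1, 2, pair = "x-y")
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_sites_total, 5L)  # low-depth site dropped
  expect_equal(out$n_snps, 3L)         # fixed diff + shared poly + reduced tri
  expect_true(out$fst > 0 && out$fst < 1)
  # dxy by hand: site1 contributes 1; site2: .6*.45+.55*.4 = 0.49;
  # site6 reduced to the two top pooled alleles A (130) and C (50):
  # ax = 50/80, ay = 80/100 -> ax(1-ay)+ay(1-ax) = .625*.2+.8*.375 = 0.425
  expect_equal(out$dxy, (1 + 0.49 + 0.425) / 5, tolerance = 1e-10)
})
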