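# independent normal-equations oracle for OLS
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

test_that("fst model recovers noise-free coefficients exactly", {
  beta <- c(0.1, 0.2, -0.3, 0.05, -0.08, -0.55)
  tab <- make_pair_table(200, beta, sigma = 0)
  # summary.lm warns on an exact fit; the exactness is the point here
  fit <- suppressWarnings(fit_fst_model(tab, model = 1))
  got <- fit$terms$beta[match(c("(Intercept)", "D1", "D2", "D1sq", "D2sq",
                                "D1xD2"), fit$terms$term)]
  expect_equal(got, beta, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("model coefficients equal the normal-equations oracle", {
  set.seed(33)
  for (r in 1:5) {
    tab <- make_pair_table(50, rnorm(6), sigma = 1, seed = 100 + r)
    fit <- fit_fst_model(tab, model = 1)
    X <- with(tab, cbind(1, D1_std, D2_std, D1_std^2, D2_std^2,
                         D1_std * D2_std))
    expect_equal(unname(fit$terms$beta), unname(drop(oracle_ols(X, tab$fst_logit))),
                 tolerance = 1e-10)
  }
})

test_that("interaction recovery under noise matched to low R2", {
  # noise sized so R^2 is near 0.12, the regime the models operate in
  beta <- c(0, 0.1, 0.1, 0, 0, -0.55)
  set.seed(44)
  n <- 10000
  d1 <- rnorm(n); d2 <- rnorm(n)
  X <- cbind(1, d1, d2, d1^2, d2^2, d1 * d2)
  signal <- drop(X %*% beta)
  sigma <- sd(signal) * sqrt(1 / 0.12 - 1)
  tab <- data.frame(gene_id = sprintf("g%05d", 1:n),
                    fst_logit = signal + rnorm(n, 0, sigma),
                    dxy_log10 = 0, D1_std = d1, D2_std = d2, fst = 0.2)
  fit <- fit_fst_model(tab, model = 1)
  ix <- fit$terms[fit$terms$term == "D1xD2", ]
  expect_lt(abs(ix$beta - (-0.55)), 3 * ix$se)
  expect_equal(fit$r_squared, 0.12, tolerance = 0.03)
})

test_that("model 2 adds covariates and flags collinearity", {
  set.seed(55)
  tab <- make_pair_table(120, rnorm(6), sigma = 0.5)
  tab$gc_content <- runif(120, 0.3, 0.6)
  tab$length <- sample(500:5000, 120)
  tab$ratio1_log10 <- rnorm(120, -1, 0.3)
  tab$ratio2_log10 <- rnorm(120, -1, 0.3)
  fit <- fit_fst_model(tab, model = 2)
  expect_true(all(c("gc_content", "gene_length", "pnps1", "pnps2") %in%
                    fit$terms$term))
  # oracle equality for the full design
  X <- with(tab, cbind(1, D1_std, D2_std, D1_std^2, D2_std^2,
                       D1_std * D2_std, gc_content, length,
                       ratio1_log10, ratio2_log10))
  expect_equal(unname(fit$terms$beta), unname(drop(oracle_ols(X, tab$fst_logit))),
               tolerance = 1e-8)
  tab$ratio2_log10 <- tab$ratio1_log10  # exact collinearity
  expect_error(fit_fst_model(tab, model = 2), "collinear")
})

test_that("dxy model separates quadratic from interaction signals", {
  # response built from negative quadratic effects only: the interaction
  # term should rarely reach significance
  set.seed(66)
  pvals <- vapply(1:100, function(r) {
    n <- 400
    d1 <- rnorm(n); d2 <- rnorm(n)
    y <- -0.3 * d1^2 - 0.3 * d2^2 + rnorm(n, 0, 0.5)
    tab <- data.frame(gene_id = sprintf("g%04d", 1:n), dxy_log10 = y,
                      fst_logit = y, D1_std = d1, D2_std = d2, fst = 0.2)
    fit <- fit_dxy_model(tab, model = 1)
    fit$terms$p[fit$terms$term == "D1xD2"]
  }, 1)
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("cohens_f2 follows its closed form and a brute-force refit", {
  f_full <- list(r_squared = 0.2); f_red <- list(r_squared = 0.1)
  expect_equal(cohens_f2(f_full, f_red), 0.125)
  expect_equal(cohens_f2(f_red, f_red), 0)
  expect_error(cohens_f2(list(r_squared = 1), f_red), "R\\^2")
  set.seed(77)
  tab <- make_pair_table(100, c(0, 0.2, 0.1, 0, 0, -0.4), sigma = 0.8)
  full <- fit_fst_model(tab, model = 1)
  red <- fit_fst_model(tab, model = 1, include_interaction = FALSE)
  # brute-force recomputation from scratch with lm
  r2f <- summary(lm(fst_logit ~ D1_std * D2_std + I(D1_std^2) +
                      I(D2_std^2), data = tab))$r.squared
  r2r <- summary(lm(fst_logit ~ D1_std + D2_std + I(D1_std^2) +
                      I(D2_std^2), data = tab))$r.squared
  expect_equal(cohens_f2(full, red), (r2f - r2r) / (1 - r2f),
               tolerance = 1e-10)
})

test_that("repeatability is exact for identical and hand-worked inputs", {
  set.seed(88)
  v <- rnorm(50)
  r <- repeatability(cbind(v, v, v))
  expect_equal(r$pc1_variance_fraction, 1)
  expect_equal(r$icc_R, 1)
  # 5-gene worked one-way ANOVA (k = 3), computed by hand:
  m <- rbind(c(1, 2, 3), c(4, 4, 4), c(0, 1, 2), c(5, 6, 4), c(2, 2, 2))
  # gene means: 2, 4, 1, 5, 2; grand mean 2.8
  # SSB = 3*((2-2.8)^2+(4-2.8)^2+(1-2.8)^2+(5-2.8)^2+(2-2.8)^2)
  #     = 3*(0.64+1.44+3.24+4.84+0.64) = 3*10.8 = 32.4 ; MSB = 32.4/4 = 8.1
  # SSW = (1+0+1)+(0)+(1+0+1)+(0+1+1)+(0) = 6 ; MSW = 6/10 = 0.6
  r <- repeatability(m)
  expect_equal(r$MS_between, 8.1)
  expect_equal(r$MS_within, 0.6)
  expect_equal(r$icc_R, (8.1 - 0.6) / (8.1 + 2 * 0.6))
  expect_equal(unname(r$df), c(4L, 10L))
  expect_error(repeatability(m[1:2, ]), ">= 3")
})

test_that("independent noise gives near-zero ICC at large n", {
  set.seed(99)
  m <- matrix(rnorm(3e4), ncol = 3)
  r <- repeatability(m)
  expect_lt(abs(r$icc_R), 0.03)
  expect_lt(abs(r$pc1_variance_fraction - 1 / 3), 0.03)
})

test_that("bin_surface produces equal margins and brute-force cell means", {
  set.seed(111)
  n <- 320
  d1 <- rnorm(n); d2 <- rnorm(n)
  stat <- -d1 * d2 + rnorm(n, 0, 0.01)
  bs <- bin_surface(d1, d2, stat)
  expect_true(all(abs(bs$marginal1 - n / 8) <= 1))
  expect_true(all(abs(bs$marginal2 - n / 8) <= 1))
  expect_equal(sum(bs$count), n)
  # brute-force group-by means
  b1 <- quantile_bins(d1, seq_len(n), 8L)
  b2 <- quantile_bins(d2, seq_len(n), 8L)
  for (i in c(1, 4, 8)) {
    for (j in c(1, 5, 8)) {
      sel <- b1 == i & b2 == j
      if (any(sel)) expect_equal(bs$mean[i, j], mean(stat[sel]))
    }
  }
  # stat = -D1*D2 peaks in the opposite-sign corners
  corners_opp <- c(bs$mean[1, 8], bs$mean[8, 1])
  corners_same <- c(bs$mean[1, 1], bs$mean[8, 8])
  expect_true(min(corners_opp) > max(corners_same))
  expect_error(bin_surface(rnorm(50), rnorm(50), rnorm(50)), "64")
})

test_that("select_imbalance applies strict thresholds deterministically", {
  tab <- data.frame(gene_id = c("g3", "g1", "g2", "g4"),
                    D1_std = c(1.5, 1.5, 0.2, NA),
                    D2_std = c(-1.5, -1.5, 0.1, 1),
                    fst = c(0.35, 0.30, 0.9, 0.9),
                    stringsAsFactors = FALSE)
  s <- select_imbalance(tab)
  expect_equal(s$genes, "g3")       # g1 fails strict fst > 0.3
  expect_equal(s$n_candidates, 3L)  # NA row not a candidate
  s <- select_imbalance(tab[0, ])
  expect_equal(s$n, 0L)
  # raw-D switch
  tab$D1_raw <- c(3, 0, 0, 0); tab$D2_raw <- c(-0.1, 0, 0, 0)
  s <- select_imbalance(tab, use_std = FALSE)
  expect_equal(s$genes, "g3")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # closed-case check: all 5 set genes carry the term among N = 20, K = 5
  universe <- sprintf("g%02d", 1:20)
  term_map <- list(T1 = universe[1:5])
  res <- hypergeom_enrichment(universe[1:5], universe, term_map)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # set = universe: p = 1 for every term -> empty result
  res <- hypergeom_enrichment(universe, universe, term_map)
  expect_equal(nrow(res), 0L)
  expect_error(hypergeom_enrichment(c("zz"), universe, term_map), "subset")
  # brute-force enumeration oracle over all draws for N <= 30
  set.seed(123)
  for (r in 1:20) {
    N <- sample(10:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    term <- sample(universe, K)
    gset <- sample(universe, n)
    k <- length(intersect(term, gset))
    # enumeration: P(X >= k) by summing the combinatorial mass
    kk <- max(0, n + K - N):min(K, n)
    mass <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
    p_exact <- sum(mass[kk >= k])
    res <- hypergeom_enrichment(gset, universe, list(T = term),
                                p_cut = 1.1, min_genes = 0L)
    expect_equal(res$p, p_exact, tolerance = 1e-12)
  }
})

test_that("class_compare detects shifts and bootstraps degenerate classes", {
  set.seed(134)
  vals <- c(rnorm(100, 1), rnorm(100, 0))
  cls <- rep(c(TRUE, FALSE), each = 100)
  res <- class_compare(vals, cls, B = 500)
  expect_lt(res$p, 1e-6)
  expect_gt(res$mean_in, res$mean_out)
  expect_true(res$ci_in[1] <= res$mean_in && res$mean_in <= res$ci_in[2])
  # constant vector: zero-width CI at the constant
  res <- class_compare(c(rep(2, 10), rnorm(50)), rep(c(TRUE, FALSE),
                                                     c(10, 50)), B = 200)
  expect_equal(res$ci_in, c(2, 2))
  expect_error(class_compare(vals, rep(c(TRUE, FALSE), c(3, 197))),
               "fewer than")
})

test_that("class_compare p-values are calibrated under the null", {
  set.seed(145)
  pv <- vapply(1:200, function(r) {
    vals <- rnorm(80)
    cls <- sample(rep(c(TRUE, FALSE), each = 40))
    class_compare(vals, cls, B = 50)$p
  }, 1)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("fixation_glm recovers known coefficients and rejects bad input", {
  set.seed(156)
  n <- 5000
  fpkm <- rlnorm(n, 3, 1)
  cls <- runif(n) < 0.3
  x <- log(fpkm) - mean(log(fpkm))
  eta <- 0.5 + 0.15 * x - 0.1 * x^2 + 0.2 * cls + 0.08 * cls * x^2
  y <- pmin(rpois(n, exp(eta)), 3L)
  fit <- fixation_glm(y, fpkm, cls, form = "quadratic")
  expect_s3_class(fit, "fixation_fit")
  expect_gt(fit$dispersion, 0)
  co <- fit$coefficients
  # recovery within 3 SE for the main curvature term (truncation at 3
  # attenuates slightly; the check is a sanity band, not exactness)
  b_x2 <- co[co$term == "x2", ]
  expect_lt(abs(b_x2$beta - (-0.1)), 3 * pmax(b_x2$se, 0.02))
  expect_equal(fit$tests$df[fit$tests$term == "class_x_sq"], 1L)
  expect_error(fixation_glm(rep(1L, 100), fpkm[1:100], cls[1:100]),
               "constant")
  expect_error(fixation_glm(c(y[-1], 5L), fpkm, cls), "0..3")
  expect_error(fixation_glm(c(y[-1], 1.5), fpkm, cls), "0..3")
})

test_that("fixation_glm class test is calibrated under a null class", {
  set.seed(167)
  pv <- vapply(1:200, function(r) {
    n <- 400
    fpkm <- rlnorm(n, 3, 1)
    cls <- sample(rep(c(TRUE, FALSE), each = n / 2))
    x <- log(fpkm) - mean(log(fpkm))
    y <- pmin(rpois(n, exp(0.3 + 0.1 * x)), 3L)
    fixation_glm(y, fpkm, cls, form = "quadratic")$tests$p[2]
  }, 1)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("poisson GLM equals an independent IRLS oracle", {
  set.seed(178)
  n <- 100
  x <- rnorm(n)
  cls <- runif(n) < 0.5
  y <- pmin(rpois(n, exp(0.2 + 0.3 * x - 0.05 * x^2 + 0.1 * cls)), 3L)
  fit <- fixation_glm(y, exp(x), cls, form = "quadratic")
  # hand-rolled IRLS for the poisson log link on the same centered design
  xc <- x - mean(x)
  Xc <- cbind(1, xc, xc^2, cls, cls * xc, cls * xc^2)
  b <- rep(0, ncol(Xc))
  for (it in 1:100) {
    eta <- drop(Xc %*% b)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    b_new <- drop(solve(t(Xc) %*% (mu * Xc), t(Xc) %*% (mu * z)))
    done <- max(abs(b_new - b)) < 1e-13
    b <- b_new
    if (done) break
  }
  got <- fit$coefficients$beta
  expect_equal(sort(abs(unname(got))), sort(abs(unname(b))),
               tolerance = 1e-6)
})

test_that("correlate matches the covariance formula and handles edge cases", {
  expect_equal(correlate(1:10, 1:10), 1)
  expect_equal(correlate(1:10, -(1:10)), -1)
  expect_true(is.nan(correlate(rep(1, 5), rnorm(5))))
  expect_error(correlate(c(1, 2, NA), c(1, NA, 3)), "complete")
  set.seed(189)
  for (r in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    r_brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlate(a, b), r_brute, tolerance = 1e-12)
  }
})

test_that("pc1_regression reports standardized betas", {
  set.seed(190)
  n <- 500
  len <- rlnorm(n, 7, 0.5)
  gc <- runif(n, 0.3, 0.6)
  y <- 0.4 * scale(len)[, 1] + rnorm(n, 0, 1)
  fit <- pc1_regression(y, data.frame(length = len, gc = gc))
  b_len <- fit$terms[fit$terms$term == "length", ]
  expect_lt(abs(b_len$beta - 0.4), 3 * b_len$se)
  # oracle: lm on standardized covariates
  ref <- coef(lm(y ~ scale(len) + scale(gc)))
  expect_equal(unname(fit$terms$beta), unname(ref), tolerance = 1e-10)
})
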