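# fixture builders shared across test files; everything is generated in code

# write a sync file from a character vector of lines
write_sync_lines <- function(lines) {
  f <- tempfile(fileext = ".sync")
  writeLines(lines, f)
  f
}

# build a sync_counts object directly from per-pool count matrices
make_sync <- function(contig, pos, counts, pool_sizes, ref = "A") {
  sync <- list(sites = data.frame(contig = contig, pos = pos,
                                  ref_base = rep_len(ref, length(pos)),
                                  stringsAsFactors = FALSE),
               counts = counts, pool_sizes = as.integer(pool_sizes))
  class(sync) <- "sync_counts"
  sync
}

count_matrix <- function(a = 0, t = 0, c = 0, g = 0, n = 0, del = 0) {
  m <- cbind(A = a, T = t, C = c, G = g, N = n, del = del)
  storage.mode(m) <- "integer"
  m
}

# one-gene annotation covering positions 1..len on contig "ctg1"
one_gene_annotation <- function(len = 100L, classes = NULL) {
  genes <- data.frame(gene_id = "gene1", contig = "ctg1", start = 0L,
                      end = len, length = len, gc_content = 0.5,
                      stringsAsFactors = FALSE)
  if (is.null(classes)) classes <- rep("NS", len)
  site_classes <- data.frame(contig = "ctg1", pos = seq_len(len),
                             gene_id = "gene1", class = classes,
                             stringsAsFactors = FALSE)
  list(genes = genes, site_classes = site_classes)
}

# independent textbook implementation of Tajima's D from a vector of
# minor-allele chromosome counts at polymorphic sites (oracle; kept free
# of package internals)
oracle_tajima_d <- function(k, n) {
  stopifnot(all(k >= 1), all(k <= n - 1))
  S <- length(k)
  # pi as the average number of pairwise differences, computed by pair
  # enumeration per site: k*(n-k) differing pairs of choose(n,2)
  pi_hat <- sum(k * (n - k)) / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson-type FST from allele frequencies (oracle for the deep-coverage
# limit of the pooled estimator): 1 - Hw/Hb with ratio-of-sums weighting
oracle_hudson_fst <- function(px, py) {
  hw <- (2 * px * (1 - px) + 2 * py * (1 - py)) / 2
  hb <- px * (1 - py) + py * (1 - px)
  keep <- hb > 0
  1 - sum(hw[keep]) / sum(hb[keep])
}

# simulate read counts for two pools at given true population frequencies
# (two-stage sampling), returning a pair_allele_counts-like table
simulate_pair_counts <- function(p_x, p_y, depth, n_pool,
                                 gene_id = "gene1") {
  ns <- length(p_x)
  yx <- rbinom(ns, n_pool, p_x) / n_pool
  yy <- rbinom(ns, n_pool, p_y) / n_pool
  cx1 <- rbinom(ns, depth, yx)
  cy1 <- rbinom(ns, depth, yy)
  out <- data.frame(gene_id = gene_id, pos = seq_len(ns),
                    cx1 = cx1, cx2 = depth - cx1,
                    cy1 = cy1, cy2 = depth - cy1,
                    ax = cx1 / depth, ay = cy1 / depth,
                    is_snp = TRUE, stringsAsFactors = FALSE)
  attr(out, "n_pool_x") <- n_pool
  attr(out, "n_pool_y") <- n_pool
  out
}

# small gene table with known structure for model tests
make_pair_table <- function(n, beta, sigma = 0, seed = 1) {
  set.seed(seed)
  d1 <- rnorm(n); d2 <- rnorm(n)
  X <- cbind(1, d1, d2, d1^2, d2^2, d1 * d2)
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  data.frame(gene_id = sprintf("g%05d", seq_len(n)), fst_logit = y,
             dxy_log10 = y, D1_std = d1, D2_std = d2,
             fst = plogis(y), stringsAsFactors = FALSE)
}
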