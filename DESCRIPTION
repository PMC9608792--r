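Package: poolfootprint
Title: Polygenic Divergence Footprints from Pool-Seq Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level population-genetic analysis of pooled sequencing
    (Pool-seq) allele counts from diverging populations. Computes per-gene,
    per-population site-frequency-spectrum statistics (segregating sites,
    Tajima's D on non-synonymous sites, piN/piS), unbiased pooled F_ST and
    absolute divergence d_XY per population pair, and the inference layer
    that links them: interaction general linear models of divergence on
    within-population Tajima's D, repeatability of differentiation (PCA and
    one-way ANOVA intraclass correlation), binned divergence surfaces,
    imbalance gene sets, hypergeometric gene-set enrichment, gene-class and
    sex-bias contrasts with bootstrap and permutation inference, and a
    quasi-Poisson fixation model. Includes a forward Wright-Fisher simulator
    of multi-gene divergence under stabilizing, directional, and balancing
    selection with a two-stage pool-sequencing emulator, so the whole
    pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
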