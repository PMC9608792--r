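---
title: "Detecting a polygenic stabilizing-selection footprint in pool-seq divergence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a polygenic stabilizing-selection footprint in pool-seq divergence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When divergent natural selection acts on one or a few large-effect loci,
population differentiation concentrates at those loci and outlier scans find
them. When net selection is *stabilizing* on highly polygenic traits, theory
predicts something very different: populations drift or adapt along ridges of
equivalent allele-frequency combinations, so differentiation is spread across
many loci, each shifted only modestly, and no locus is an outlier. The
detectable trace of this regime is not a peak in F\_ST but a pattern of
*covariation* across genes: a gene that contributes to differentiation tends
to show a sweep-like site-frequency spectrum (excess of rare variants,
negative Tajima's D) in one population while the same gene shows a
balancing-like spectrum (excess of intermediate-frequency variants, positive
D) in the other. `poolfootprint` implements the full inference chain for this
signal from pooled sequencing (pool-seq) allele counts, plus a forward
simulator that generates data under the competing scenarios so that every
stage can be validated without any external dataset.

## Statistics computed per gene

**Within populations** (module `gene_sfs_stats`): for each gene and
population we compute the number of segregating non-synonymous sites `S`, the
two estimators of the scaled mutation rate —
$\hat\theta_\pi = \sum_s 2\hat p_s(1-\hat p_s)\,n_e/(n_e-1)$ and
$\hat\theta_W = S/a_1$ — and Tajima's
$D = (\hat\theta_\pi - \hat\theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$ with the
standard constants $a_1,a_2,b_1,b_2,c_1,c_2,e_1,e_2$ evaluated at the
effective sample size, plus per-site diversity at non-synonymous and
synonymous sites and $\log_{10}(\pi_N/\pi_S)$. Statistics are folded
(minor-allele frequencies; no ancestral polarization), which is what makes
Tajima's D usable without an outgroup. D is reported both raw and
standardized to mean 0, variance 1 across all genes of a population — the
standardized scale is what the models use, because the raw absolute value of
D is confounded by demography that all genes share.

Pool-seq adds two layers of sampling between population frequencies and read
counts: individuals into the pool, reads from the pool. We do not
reimplement a full pool-aware estimator stack; instead the effective number
of chromosomes per site is `n_eff = min(haploid pool size, depth)`, the
ceiling imposed by two-stage sampling, and gene-level formulas are evaluated
at the gene's median site `n_eff`. This is an approximation, declared as
such; its correctness anchor is the no-pooling limit, where the estimators
agree with a textbook genotype-count implementation to 1e-10 (enforced by
test).

**Between populations** (module `divergence_pair`): relative divergence uses
the unbiased identity-probability formulation for pools. For a biallelic SNP
with read counts $c_1, c_2$ ($c = c_1+c_2$) in a pool of $n$ haploid
genomes, the within-pool read identity
$F = [c_1(c_1-1) + c_2(c_2-1)]/[c(c-1)]$ has expectation
$1/n + (1-1/n)Q_1$, because two distinct reads resample the same pool
chromosome with probability $1/n$; inverting gives the unbiased
$\hat Q_1 = (nF-1)/(n-1)$. Reads from different pools never share a
chromosome, so the cross-pool read identity estimates $Q_2$ without
correction. The gene-level estimate is the ratio of sums across SNPs,
$\hat F_{ST} = (\bar Q_1 - \bar Q_2)/(1 - \bar Q_2)$ — the standard
multilocus aggregation, which equals summing numerators and denominators.
Slightly negative estimates are retained raw (class means stay unbiased) and
clamped only for the logit transform. Absolute divergence is
$d_{XY} = \sum_s (A_X B_Y + A_Y B_X) / \text{(total sites)}$ with pool read
frequencies, the denominator counting *all* sites in the gene passing depth
filters in both pools, variable or not. F\_ST is logit- and d\_XY
log10-transformed before modeling.

**Site filters.** Sites are reduced to their two highest-count alleles
(three or more alleles at calling depth: site dropped, counted); a minor
allele needs `min_minor_count = 2` reads, sites below it stay in the
denominators as monomorphic; the depth window is `[10, 500]`. D needs at
least `min_snps = 3` segregating sites, below which the normalizer is
unstable and D is `NaN`; such genes drop out of models listwise.

A consequence worth knowing: at 125x depth the 2-read minor-allele floor
censors folded frequencies below roughly 0.015. This ascertainment removes
part of the rare tail of every gene's spectrum and shifts *raw* neutral D
upward (about +0.6 under our neutral calibration). It affects all genes of a
population alike, which is exactly why the models operate on
across-gene-standardized D; the equilibrium property "mean raw D near 0" is
therefore asserted in the deep-coverage limit where the filter keeps the
full spectrum.

## The inference layer

* **Interaction models.** Per population pair, OLS of logit F\_ST (and of
  log10 d\_XY) on standardized $D_1, D_2$, their squares, and $D_1 \times
  D_2$; model 2 adds GC content, gene length and both populations'
  $\log_{10}(\pi_N/\pi_S)$. A *negative* interaction coefficient is the
  footprint: opposite-signed D pairs carry high relative divergence. The
  effect size of the interaction is Cohen's
  $f^2 = (R^2_{full}-R^2_{reduced})/(1-R^2_{full})$.
* **Repeatability.** PCA (covariance, columns centered — a switch allows
  correlation PCA) of the three aligned per-gene divergence vectors, and the
  one-way ANOVA intraclass correlation
  $R = (MS_B - MS_W)/(MS_B + (k-1)MS_W)$ with gene as the factor, $k = 3$
  pairs; negative estimates are reported as-is.
* **Binned surfaces.** Genes are binned into octiles along each
  population's standardized D (ties broken by gene id; equal counts ±1) and
  the 8×8 grid of mean divergence visualizes the interaction; thin cells
  (<5 genes) are flagged.
* **Imbalance sets.** Genes with $|D_1 - D_2| > 2.5$ (standardized scale by
  default; a switch selects raw D) *and* raw F\_ST > 0.3, both strict.
* **Enrichment.** Upper-tail hypergeometric over-representation of
  user-supplied terms in a gene set against a universe; raw p < .05 by
  default, Benjamini–Hochberg available behind a flag.
* **Class and sex-bias contrasts.** Welch's t against the complement with
  bias-corrected percentile bootstrap CIs (B = 2000) of class means;
  female- and male-biased genes split into |log2FC| quartiles (8 bins), a
  one-way F statistic referred to its label-permutation distribution
  (10,000 permutations, add-one p).
* **Fixation model.** The number of populations (0–3) still segregating
  non-synonymous variation per gene, modeled as Poisson log-link GLM with
  an empirical dispersion factor (Pearson $\chi^2$/df); either nine
  equal-count FPKM bins crossed with a gene-class flag, or mean-centered
  log FPKM plus its square with class interactions. Term tests are
  dispersion-scaled likelihood-ratio statistics referred to $\chi^2$ (the
  quasi-likelihood convention, recorded in the output).

Missing data policy is listwise deletion per model, so different models run
on different gene counts — the per-model `n` is always reported.

## The synthetic study system

`scenario_config()` fixes the conditions the generator emulates: three
populations of N = 500 diploids split simultaneously from a common ancestor
for 300 generations; 300 genes of 2 kb with 80 non-synonymous and 40
synonymous mutable loci each (the remaining positions are emitted as
monomorphic sites so absolute-divergence denominators are honest); reversible
per-site mutation at `mu = 1.1e-5` so that $4N\mu = 0.022$ matches the
synonymous diversity of the motivating system, which together with the locus
count yields an observed coding SNP density near 6/kb after pool
ascertainment; pools of 400 haploid genomes (200 diploid males) at
Poisson-125x depth. At these values 300 neutral generations give mean F\_ST
near $1-(1-1/2N)^t \approx 0.26$, the differentiation scale of interest.

Frequencies are initialized at the stationary distribution of the
reversible-mutation drift process (Beta($4N\mu$, $4N\mu$)) rather than burnt
in from a fixed state; the default burn-in is therefore 500 generations
(~N), enough to settle the selected scenarios, instead of the 8N
rule-of-thumb that stationary initialization makes redundant.

Scenarios: `NEUTRAL_INDEPENDENT` (pure drift), `STABILIZING_SHARED` /
`STABILIZING_SHIFTED` (gene-level additive trait $z=\sum\alpha g$ with
exponential effect sizes and Gaussian viability
$w = \exp(-(z-\theta)^2/2\omega^2)$, optima equal or shifted after the
split), and `DISCORDANT_ENGINEERED` — the deterministic generator of the
footprint pattern. In the engineered scenario a labeled fraction (default
25%) of genes receives, at their intermediate-frequency non-synonymous loci
(split-time minor frequency > 0.05): *directional* selection with
`s_dir = 0.01` in the gene's sweep population — randomly population 1 or 2,
since the imbalance runs in either direction — and *heterozygote advantage*
with `s_het = 0.1` in the other. The directional coefficient is chosen so
that $s \cdot t \approx 3$ logit units — the sweeps are deliberately
*incomplete* at sampling time, leaving the driven alleles at high but
unfixed frequencies whose folded values (0.01–0.1) are an observable excess
of rare variants. (A completed sweep would be invisible here: with free
recombination between loci there is no linked diversity trough, so a fixed
locus simply leaves the spectrum.) The balancing population holds the same
loci near 1/2 and accumulates newly arising balanced variants, giving
positive D. High F\_ST between the two follows from the frequency gap at the
engineered loci. Engineering both imbalance directions matters statistically:
with clusters in both opposite-sign corners of the (D1, D2) plane, the
product term — not the main effects — uniquely carries the divergence
signal, which is exactly the structure the interaction model tests.

Implementation: unlinked neutral loci are advanced by the exact binomial
allele-frequency form of the diploid Wright–Fisher process — under random
mating the next-generation count at an unlinked neutral locus is
Binomial(2N, p) however individuals are formed — while loci under selection
use a diploid individual-based kernel (selection acts on whole individuals).
One simplification is accepted: fitness variance among parents slightly
inflates drift even at unlinked neutral loci (fertility-variance effect);
this second-order effect is ignored for neutral loci of selected genes.
Populations are re-founded from frequencies at epoch boundaries, equivalent
to one extra binomial generation. All randomness descends from the single
config seed; equal configs are bit-reproducible.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage and linked selection (loci are free-
recombining by construction), demographic history beyond a clean
simultaneous split, gene flow, sequencing error and mapping artifacts,
variation in gene length or site-class composition, and any real
transcriptome structure (expression tables are independent log-normal draws
used to exercise the binning and fixation machinery, not to emulate
expression biology).

## Numerical choices and degenerate inputs

Logit clamping at `1e-4` and a d\_XY floor of `1e-6` keep transforms finite;
raw columns always retain the unclamped values. Quantile bins use a stable
sort on (value, gene id), so ties are deterministic and marginal counts
differ by at most one. Zero-variance D vectors, constant fixation responses,
rank-deficient designs (named offending columns), classes below five
members, and sub-64-gene surfaces are errors, not silent results. Bootstrap
bias correction clamps the correction factor away from ±∞ when all
resamples fall on one side. The Q1 estimator needs at least two reads of the
retained alleles per pool; sites failing that are unusable and dropped from
the pair. Problem sizes in the test-suite and acceptance runs (300 genes,
N = 500, 10 seeds for the effect-size contrast, 200 replicates for
calibration checks) are the package's chosen desk-scale study conditions.

## Known limitations

The `n_eff` approximation understates the extra variance of two-stage
sampling relative to a full pool-aware likelihood; the D ascertainment shift
at field-typical depth is real and documented above; the fixation response
caps at three populations and carries little information when almost all
genes segregate everywhere; and the engineered discordant scenario is a
caricature — it demonstrates that the inference layer recovers the pattern
the theory predicts, not that real divergence was generated that way.
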