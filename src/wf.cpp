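#include <Rcpp.h>
using namespace Rcpp;

// Forward Wright-Fisher kernels.
//
// Two representations are used:
//  * allele-frequency kernel for unlinked neutral loci (exact: under random
//    mating the next-generation allele count at an unlinked neutral locus is
//    Binomial(2N, p) regardless of how individuals are formed);
//  * diploid individual-based kernel for loci under selection, where fitness
//    acts on whole individuals.
// Both draw from R's RNG so set.seed() governs everything.

// Reversible biallelic mutation applied to a frequency.
static inline double mutate_freq(double p, double mu) {
  return p * (1.0 - mu) + (1.0 - p) * mu;
}

//' @name wf_neutral_freq
//' @noRd
// [[Rcpp::export(rng = true)]]
NumericVector wf_neutral_freq(NumericVector p0, int N, double mu,
                              int generations) {
  int L = p0.size();
  NumericVector p = clone(p0);
  double n2 = 2.0 * N;
  for (int t = 0; t < generations; ++t) {
    for (int l = 0; l < L; ++l) {
      double pm = mutate_freq(p[l], mu);
      // skip the draw when the locus is fixed and cannot mutate back this
      // generation (pm exactly 0 or 1): rbinom would return the same state
      if (pm <= 0.0) { p[l] = 0.0; continue; }
      if (pm >= 1.0) { p[l] = 1.0; continue; }
      p[l] = R::rbinom(n2, pm) / n2;
    }
  }
  return p;
}

// sample an index from cumulative weights via binary search
static inline int sample_cum(const std::vector<double>& cum, double u) {
  int lo = 0, hi = (int)cum.size() - 1;
  double target = u * cum[hi];
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < target) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Diploid individual-based WF for one gene. A1, A2: N x L 0/1 allele
// matrices (two haplotypes per individual). Selection modes:
//   0 neutral, 1 stabilizing on additive trait z = sum(alpha * genotype),
//   2 directional (fitness (1+s)^[# copies of the favored allele at sel loci],
//     fav[k] in {0,1} names the favored allele per selected locus),
//   3 heterozygote advantage (fitness (1+s)^[# heterozygous sel loci]).
//' @noRd
// [[Rcpp::export(rng = true)]]
List wf_gene_evolve(IntegerMatrix A1, IntegerMatrix A2,
                    int mode, IntegerVector sel_idx, IntegerVector fav,
                    NumericVector alpha,
                    double opt, double omega, double s,
                    double mu, int generations) {
  int N = A1.nrow(), L = A1.ncol();
  int K = sel_idx.size();
  IntegerMatrix B1(N, L), B2(N, L);
  // work on copies so the caller's matrices are untouched
  IntegerMatrix C1 = clone(A1), C2 = clone(A2);
  int *c1 = INTEGER(SEXP(C1)), *c2 = INTEGER(SEXP(C2));
  int *b1 = INTEGER(SEXP(B1)), *b2 = INTEGER(SEXP(B2));
  std::vector<double> cum(N);
  double exp_mut = 2.0 * N * L * mu;

  for (int t = 0; t < generations; ++t) {
    bool weighted = (mode != 0);
    if (weighted) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        double w;
        if (mode == 1) {
          double z = 0.0;
          for (int k = 0; k < K; ++k) {
            int l = sel_idx[k] * N;
            z += alpha[k] * (c1[i + l] + c2[i + l]);
          }
          double d = z - opt;
          w = std::exp(-(d * d) / (2.0 * omega * omega));
        } else if (mode == 2) {
          int cnt = 0;
          for (int k = 0; k < K; ++k) {
            int l = sel_idx[k] * N;
            int g = c1[i + l] + c2[i + l];
            cnt += (fav[k] == 1) ? g : 2 - g;
          }
          w = std::pow(1.0 + s, cnt);
        } else {
          int het = 0;
          for (int k = 0; k < K; ++k) {
            int l = sel_idx[k] * N;
            het += (c1[i + l] != c2[i + l]) ? 1 : 0;
          }
          w = std::pow(1.0 + s, het);
        }
        acc += w;
        cum[i] = acc;
      }
      if (!(acc > 0.0)) weighted = false;  // fitness collapse: fall back
    }
    for (int i = 0; i < N; ++i) {
      int mom, dad;
      if (weighted) {
        mom = sample_cum(cum, unif_rand());
        dad = sample_cum(cum, unif_rand());
      } else {
        mom = (int)(unif_rand() * N); if (mom == N) mom = N - 1;
        dad = (int)(unif_rand() * N); if (dad == N) dad = N - 1;
      }
      for (int l = 0; l < L; ++l) {
        int off = l * N;
        int gm = c1[mom + off] + c2[mom + off];
        int gd = c1[dad + off] + c2[dad + off];
        // transmitted allele: deterministic unless heterozygous
        b1[i + off] = (gm == 1) ? (unif_rand() < 0.5 ? 1 : 0) : gm / 2;
        b2[i + off] = (gd == 1) ? (unif_rand() < 0.5 ? 1 : 0) : gd / 2;
      }
    }
    // sparse reversible mutation in the offspring
    int nmut = (int)R::rpois(exp_mut);
    for (int m = 0; m < nmut; ++m) {
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      int l = (int)(unif_rand() * L); if (l == L) l = L - 1;
      if (unif_rand() < 0.5) b1[i + l * N] = 1 - b1[i + l * N];
      else                   b2[i + l * N] = 1 - b2[i + l * N];
    }
    std::swap(c1, b1);
    std::swap(c2, b2);
  }
  // after an odd number of generations the data live in the B buffers
  if (generations % 2 == 1) {
    return List::create(_["A1"] = B1, _["A2"] = B2);
  }
  return List::create(_["A1"] = C1, _["A2"] = C2);
}
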