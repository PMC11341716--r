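#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All pairwise Bray-Curtis dissimilarities of the rows of m, accumulated
// column-wise (m is column-major). A double-zero pair is defined as 0; this
// can only arise inside permuted matrices, never on pooled input rows.
// Writes the sorted profile into prof (resized to n*(n-1)/2).
static void profile_of(const double *m, int n, int p,
                       std::vector<double> &s_min, std::vector<double> &s_sum,
                       std::vector<double> &prof) {
  int npairs = n * (n - 1) / 2;
  s_min.assign(npairs, 0.0);
  s_sum.assign(npairs, 0.0);
  for (int k = 0; k < p; ++k) {
    const double *col = m + (size_t)k * n;
    int q = 0;
    for (int i = 0; i < n - 1; ++i) {
      double u = col[i];
      for (int j = i + 1; j < n; ++j, ++q) {
        double v = col[j];
        s_min[q] += (u < v) ? u : v;
        s_sum[q] += u + v;
      }
    }
  }
  prof.resize(npairs);
  for (int q = 0; q < npairs; ++q) {
    prof[q] = (s_sum[q] <= 0.0) ? 0.0 : 1.0 - 2.0 * s_min[q] / s_sum[q];
  }
  std::sort(prof.begin(), prof.end());
}

// In-place Fisher-Yates shuffle of each column independently, using R's RNG
// so that set.seed() in R controls reproducibility.
static void permute_columns(double *m, int n, int p) {
  for (int k = 0; k < p; ++k) {
    double *col = m + (size_t)k * n;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(col[i], col[j]);
    }
  }
}

// SIMPROF permutation engine: observed similarity profile, rank-wise mean
// expected profile under independent within-species permutation, the pi
// deviation statistic, and a Monte Carlo null distribution of pi.
// [[Rcpp::export(name = ".simprof_engine")]]
List simprof_engine(NumericMatrix m, int n_expected, int n_null) {
  int n = m.nrow(), p = m.ncol();
  int npairs = n * (n - 1) / 2;
  std::vector<double> s_min, s_sum, obs, prof;
  profile_of(m.begin(), n, p, s_min, s_sum, obs);

  RNGScope scope;
  std::vector<double> work(m.begin(), m.end());

  // Expected profile: rank-wise mean over n_expected permuted profiles.
  std::vector<double> expected(npairs, 0.0);
  for (int r = 0; r < n_expected; ++r) {
    permute_columns(work.data(), n, p);
    profile_of(work.data(), n, p, s_min, s_sum, prof);
    for (int q = 0; q < npairs; ++q) expected[q] += prof[q];
  }
  for (int q = 0; q < npairs; ++q) expected[q] /= n_expected;

  double pi_obs = 0.0;
  for (int q = 0; q < npairs; ++q) pi_obs += std::fabs(obs[q] - expected[q]);

  // Null pi values: further permutations scored against the same expected
  // profile.
  NumericVector pi_null(n_null);
  for (int r = 0; r < n_null; ++r) {
    permute_columns(work.data(), n, p);
    profile_of(work.data(), n, p, s_min, s_sum, prof);
    double pi = 0.0;
    for (int q = 0; q < npairs; ++q) pi += std::fabs(prof[q] - expected[q]);
    pi_null[r] = pi;
  }

  return List::create(
    _["observed"] = NumericVector(obs.begin(), obs.end()),
    _["expected"] = NumericVector(expected.begin(), expected.end()),
    _["pi_obs"] = pi_obs,
    _["pi_null"] = pi_null);
}

// [[Rcpp::export(name = ".bray_curtis_matrix")]]
NumericMatrix bray_curtis_matrix(NumericMatrix m) {
  int n = m.nrow(), p = m.ncol();
  std::vector<double> s_min, s_sum, prof;
  int npairs = n * (n - 1) / 2;
  s_min.assign(npairs, 0.0);
  s_sum.assign(npairs, 0.0);
  const double *mm = m.begin();
  for (int k = 0; k < p; ++k) {
    const double *col = mm + (size_t)k * n;
    int q = 0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j, ++q) {
        double u = col[i], v = col[j];
        s_min[q] += (u < v) ? u : v;
        s_sum[q] += u + v;
      }
    }
  }
  NumericMatrix d(n, n);
  int q = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++q) {
      double val = (s_sum[q] <= 0.0) ? 0.0 : 1.0 - 2.0 * s_min[q] / s_sum[q];
      d(i, j) = d(j, i) = val;
    }
  }
  return d;
}
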