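#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sample entropy of a raw double buffer. Richman–Moorman bookkeeping:
// both the m and the m+1 comparisons run over the first n-m templates,
// pairs i != j counted once, self-matches excluded, Chebyshev distance.
//
// Exact sorted-window algorithm: templates are enumerated in order of
// their first component, so for template i only the contiguous block of
// templates whose first component lies within the tolerance needs the
// remaining component comparisons. Identical counts to the naive double
// loop, typically several-fold faster at MSE tolerances.
static double sampen_buf(const double* v, int n, int m, double tol) {
  const int nt = n - m;            // templates with m+1 points available
  if (nt < 2) return NA_REAL;
  std::vector<int> idx(nt);
  for (int i = 0; i < nt; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [v](int a, int b) { return v[a] < v[b]; });
  long long A = 0, B = 0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = idx[a];
    const double lim = v[i] + tol;
    for (int b = a + 1; b < nt && v[idx[b]] <= lim; ++b) {
      const int j = idx[b];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) > tol) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(v[i + m] - v[j + m]) <= tol) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}

// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double tol) {
  return sampen_buf(REAL(x), x.size(), m, tol);
}

// mean log of self-match-inclusive template match frequencies
static double apen_phi(const double* v, int n, int m, double tol) {
  const int nt = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) > tol) { match = false; break; }
      }
      if (match) ++cnt;            // includes j == i
    }
    acc += std::log(static_cast<double>(cnt) / static_cast<double>(nt));
  }
  return acc / nt;
}

// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double tol) {
  const double* v = REAL(x);
  const int n = x.size();
  return apen_phi(v, n, m, tol) - apen_phi(v, n, m + 1, tol);
}

// MSE over integer scales: non-overlapping block means, then SampEn with a
// fixed tolerance (anchored to the SD of the original series by the caller).
// Scales with too few coarse-grained points come back NA.
// [[Rcpp::export]]
NumericVector cpp_mse(NumericVector x, IntegerVector scales, int m, double tol) {
  const int n = x.size();
  const double* v = REAL(x);
  NumericVector out(scales.size(), NA_REAL);
  std::vector<double> y;
  for (int si = 0; si < scales.size(); ++si) {
    const int s = scales[si];
    if (s < 1) continue;
    const int ny = n / s;
    if (ny < m + 2) continue;
    y.resize(ny);
    for (int j = 0; j < ny; ++j) {
      double acc = 0.0;
      for (int k = 0; k < s; ++k) acc += v[j * s + k];
      y[j] = acc / s;
    }
    out[si] = sampen_buf(y.data(), ny, m, tol);
  }
  return out;
}
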