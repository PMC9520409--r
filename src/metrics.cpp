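#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sample-entropy pair counts (Richman & Moorman convention, raw-sum ratio).
// Templates of length m and m+1 both start at i = 0..N-m-1; a template is
// omitted if it contains an excluded interval.  Matching uses Chebyshev
// distance strictly below tol.  Returns c(B_m, B_{m+1}) over ordered pairs.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, LogicalVector valid, int m,
                                double tol) {
  const int N = x.size();
  const int M = N - m;
  long long bm = 0, bm1 = 0;
  if (M >= 1) {
    std::vector<char> vm(M), vm1(M);
    for (int i = 0; i < M; ++i) {
      bool ok = true;
      for (int k = 0; k < m; ++k)
        if (!valid[i + k]) { ok = false; break; }
      vm[i] = ok;
      vm1[i] = ok && valid[i + m];
    }
    const double* xx = REAL(x);
    for (int i = 0; i < M; ++i) {
      if (!vm[i]) continue;
      for (int j = i + 1; j < M; ++j) {
        if (!vm[j]) continue;
        bool match = true;
        for (int k = 0; k < m; ++k)
          if (std::fabs(xx[i + k] - xx[j + k]) >= tol) { match = false; break; }
        if (!match) continue;
        bm += 2; // ordered pairs (i,j) and (j,i)
        if (vm1[i] && vm1[j] && std::fabs(xx[i + m] - xx[j + m]) < tol)
          bm1 += 2;
      }
    }
  }
  return NumericVector::create((double)bm, (double)bm1);
}

// Sliding-window sample entropy over trailing windows of N intervals.
// Tolerance is r times the window's own sample std (n-1 denominator, valid
// intervals only).  Windows with undefined entropy yield NA.
// [[Rcpp::export]]
NumericVector cpp_sampen_trend(NumericVector x, LogicalVector valid, int m,
                               double r, int N) {
  const int L = x.size();
  const int nw = L - N + 1;
  NumericVector out(nw, NA_REAL);
  for (int s = 0; s < nw; ++s) {
    // window std over valid entries
    double sum = 0.0, sum2 = 0.0;
    int nv = 0;
    for (int i = s; i < s + N; ++i) {
      if (valid[i]) { sum += x[i]; sum2 += x[i] * x[i]; ++nv; }
    }
    if (nv < 2) continue;
    double var = (sum2 - sum * sum / nv) / (nv - 1);
    if (!(var > 0.0)) continue;
    NumericVector cnt = cpp_sampen_counts(
        x[Range(s, s + N - 1)],
        valid[Range(s, s + N - 1)], m, r * std::sqrt(var));
    if (cnt[0] > 0 && cnt[1] > 0) out[s] = -std::log(cnt[1] / cnt[0]);
  }
  return out;
}

static double ks_sorted(const double* a, int n, const double* b, int m) {
  int i = 0, j = 0;
  double d = 0.0;
  while (i < n && j < m) {
    double v = std::min(a[i], b[j]);
    while (i < n && a[i] == v) ++i;
    while (j < m && b[j] == v) ++j;
    double diff = std::fabs((double)i / n - (double)j / m);
    if (diff > d) d = diff;
  }
  return d;
}

// [[Rcpp::export]]
double cpp_ks(NumericVector a, NumericVector b) {
  std::vector<double> sa(a.begin(), a.end()), sb(b.begin(), b.end());
  std::sort(sa.begin(), sa.end());
  std::sort(sb.begin(), sb.end());
  return ks_sorted(sa.data(), sa.size(), sb.data(), sb.size());
}

// KS distance between one sorted sample and each (sorted) column of a matrix.
// [[Rcpp::export]]
NumericVector cpp_ks_vs_cols(NumericVector cond_sorted, NumericMatrix cols_sorted) {
  const int D = cols_sorted.ncol(), n = cols_sorted.nrow();
  NumericVector out(D);
  for (int d = 0; d < D; ++d)
    out[d] = ks_sorted(REAL(cond_sorted), cond_sorted.size(),
                       &cols_sorted(0, d), n);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sort_cols(NumericMatrix m) {
  NumericMatrix out = clone(m);
  for (int j = 0; j < out.ncol(); ++j)
    std::sort(&out(0, j), &out(0, j) + out.nrow());
  return out;
}
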