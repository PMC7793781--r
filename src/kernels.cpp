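#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ordered-pair template match counts for sample entropy (Chebyshev distance,
// self-matches excluded). Both template lengths are counted over the same
// index range i <= N - m, so the length-(m+1) count reuses the length-m
// distance and extends it by one coordinate. Templates are sorted by their
// first coordinate so that only pairs within tolerance on it are visited:
// the enumerated pair set (and therefore the counts) is exactly that of the
// naive double loop.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int n = N - m;
  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double B = 0.0, A = 0.0;
  for (int a = 0; a < n - 1; a++) {
    int i = idx[a];
    for (int b = a + 1; b < n && x[idx[b]] - x[i] <= r; b++) {
      int j = idx[b];
      bool within = true;
      for (int k = 1; k < m; k++) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { within = false; break; }
      }
      if (within) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  // unordered pairs doubled to ordered-pair counts
  return NumericVector::create(2.0 * B, 2.0 * A);
}

// Iterate x(t) = sum_k A_k x(t-k) + eps(t); A is a list of C x C lag
// matrices, eps the pre-drawn innovation matrix (C x n).
// [[Rcpp::export]]
NumericMatrix simulate_var_cpp(List A, NumericMatrix eps, int p) {
  int C = eps.nrow(), n = eps.ncol();
  NumericMatrix x(C, n);
  std::vector<NumericMatrix> Ak(p);
  for (int k = 0; k < p; k++) Ak[k] = as<NumericMatrix>(A[k]);
  for (int t = 0; t < n; t++) {
    for (int i = 0; i < C; i++) x(i, t) = eps(i, t);
    for (int k = 0; k < p && k < t; k++) {
      int s = t - k - 1;
      for (int i = 0; i < C; i++) {
        double acc = 0.0;
        for (int j = 0; j < C; j++) acc += Ak[k](i, j) * x(j, s);
        x(i, t) += acc;
      }
    }
  }
  return x;
}
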