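#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Asymmetric least squares baseline (Eilers & Boelens style).
// Solves (W + lam * D2'D2) z = W y iteratively, where D2 is the second
// difference operator; weights are p for points above the baseline and 1-p
// below. The system matrix is symmetric pentadiagonal, so an O(n) banded
// LDL^T factorisation is used instead of a generic sparse solver.
// [[Rcpp::export]]
NumericVector als_baseline_cpp(NumericVector y, double lam, double p,
                               int n_iter) {
  const int m = y.size();
  if (m < 5) stop("spectrum too short for baseline estimation (need >= 5 points)");
  if (lam <= 0 || p <= 0 || p >= 1 || n_iter < 1)
    stop("require lam > 0, 0 < p < 1, n_iter >= 1");

  // pentadiagonal bands of lam * D2'D2
  std::vector<double> d0(m), d1(m - 1), d2(m - 2);
  for (int i = 0; i < m; ++i) {
    double v = (i == 0 || i == m - 1) ? 1.0 : (i == 1 || i == m - 2) ? 5.0 : 6.0;
    d0[i] = lam * v;
  }
  for (int i = 0; i < m - 1; ++i)
    d1[i] = lam * ((i == 0 || i == m - 2) ? -2.0 : -4.0);
  for (int i = 0; i < m - 2; ++i) d2[i] = lam;

  std::vector<double> w(m, 1.0), z(m, 0.0), D(m), L1(m, 0.0), L2(m, 0.0),
      c(m);
  for (int iter = 0; iter < n_iter; ++iter) {
    // banded LDL^T of A = diag(w) + penalty
    for (int i = 0; i < m; ++i) {
      double di = d0[i] + w[i];
      if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
      if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
      D[i] = di;
      if (i < m - 1) {
        double l1 = d1[i];
        if (i >= 1) l1 -= L2[i - 1] * L1[i - 1] * D[i - 1];
        L1[i] = l1 / di;
      }
      if (i < m - 2) L2[i] = d2[i] / di;
    }
    // forward solve L c = W y
    for (int i = 0; i < m; ++i) {
      double v = w[i] * y[i];
      if (i >= 1) v -= L1[i - 1] * c[i - 1];
      if (i >= 2) v -= L2[i - 2] * c[i - 2];
      c[i] = v;
    }
    for (int i = 0; i < m; ++i) c[i] /= D[i];
    // back solve L^T z = c
    for (int i = m - 1; i >= 0; --i) {
      double v = c[i];
      if (i + 1 < m) v -= L1[i] * z[i + 1];
      if (i + 2 < m) v -= L2[i] * z[i + 2];
      z[i] = v;
    }
    for (int i = 0; i < m; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
  }
  return NumericVector(z.begin(), z.end());
}
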