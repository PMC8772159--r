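#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric-least-squares baseline estimation (Whittaker smoother with
// asymmetric weights), one trace per column. The normal equations
// (W + lambda * D'D) z = W y with D the second-difference operator form a
// pentadiagonal SPD system, solved by a banded LDL^T factorization in O(n)
// per iteration.

static void pentasolve(const std::vector<double>& d0,
                       const std::vector<double>& d1,
                       const std::vector<double>& d2,
                       std::vector<double>& b,
                       std::vector<double>& dd,
                       std::vector<double>& l1,
                       std::vector<double>& l2) {
  const int n = (int)d0.size();
  for (int i = 0; i < n; ++i) {
    double a2 = (i >= 2) ? d2[i - 2] : 0.0;  // A(i, i-2)
    double a1 = (i >= 1) ? d1[i - 1] : 0.0;  // A(i, i-1)
    if (i >= 2) l2[i] = a2 / dd[i - 2];
    if (i >= 1) {
      double t = a1;
      if (i >= 2) t -= l2[i] * l1[i - 1] * dd[i - 2];
      l1[i] = t / dd[i - 1];
    }
    double di = d0[i];
    if (i >= 1) di -= l1[i] * l1[i] * dd[i - 1];
    if (i >= 2) di -= l2[i] * l2[i] * dd[i - 2];
    dd[i] = di;
  }
  for (int i = 0; i < n; ++i) {          // forward: L u = b
    if (i >= 1) b[i] -= l1[i] * b[i - 1];
    if (i >= 2) b[i] -= l2[i] * b[i - 2];
  }
  for (int i = 0; i < n; ++i) b[i] /= dd[i];
  for (int i = n - 1; i >= 0; --i) {     // backward: L' z = v
    if (i + 1 < n) b[i] -= l1[i + 1] * b[i + 1];
    if (i + 2 < n) b[i] -= l2[i + 2] * b[i + 2];
  }
}

// [[Rcpp::export]]
NumericMatrix als_baseline_mat(NumericMatrix y, double lambda, double p,
                               int niter) {
  const int n = y.nrow(), m = y.ncol();
  if (n < 3) stop("trace too short for a second-difference penalty");
  NumericMatrix z(n, m);
  // lambda * D'D bands (constant across columns and iterations)
  std::vector<double> p0(n), p1(n - 1), p2(n - 2);
  for (int i = 0; i < n; ++i) {
    double v = 0.0;
    if (i <= n - 3) v += 1.0;
    if (i >= 1 && i <= n - 2) v += 4.0;
    if (i >= 2) v += 1.0;
    p0[i] = lambda * v;
  }
  for (int i = 0; i < n - 1; ++i) {
    double v = 0.0;
    if (i <= n - 3) v += -2.0;
    if (i >= 1 && i <= n - 2) v += -2.0;
    p1[i] = lambda * v;
  }
  for (int i = 0; i < n - 2; ++i) p2[i] = lambda * 1.0;

  std::vector<double> d0(n), b(n), w(n), dd(n), l1(n, 0.0), l2(n, 0.0);
  for (int j = 0; j < m; ++j) {
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < niter; ++it) {
      for (int i = 0; i < n; ++i) {
        d0[i] = p0[i] + w[i];
        b[i] = w[i] * y(i, j);
      }
      pentasolve(d0, p1, p2, b, dd, l1, l2);
      for (int i = 0; i < n; ++i) w[i] = (y(i, j) > b[i]) ? p : 1.0 - p;
    }
    for (int i = 0; i < n; ++i) z(i, j) = b[i];
  }
  return z;
}
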