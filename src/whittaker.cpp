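#include <Rcpp.h>
using namespace Rcpp;

// Weighted Whittaker smoother with a second-difference penalty:
// solve (W + lambda * D2' D2) z = W y for z, where W = diag(w) and D2 is
// the (n-2) x n second-difference operator. The system matrix is
// pentadiagonal SPD, solved by a banded Cholesky factorization in O(n).
// This is the inner solve of airPLS, called once per reweighting
// iteration for every pixel of a map, hence compiled.

// [[Rcpp::export]]
NumericVector whittaker_solve(NumericVector y, NumericVector w, double lambda) {
  const int n = y.size();
  if (w.size() != n) stop("weight vector length must match signal length");
  if (n < 3) stop("signal too short for a second-difference penalty");
  if (lambda <= 0) stop("lambda must be positive");

  // assemble bands of A = W + lambda * D2'D2
  std::vector<double> a0(n), a1(n - 1, 0.0), a2(n - 2, 0.0);
  for (int i = 0; i < n; ++i) a0[i] = w[i];
  // rows k = 0..n-3 of D2 have (1, -2, 1) at columns k, k+1, k+2
  for (int k = 0; k <= n - 3; ++k) {
    a0[k]     += lambda * 1.0;
    a0[k + 1] += lambda * 4.0;
    a0[k + 2] += lambda * 1.0;
    a1[k]     += lambda * -2.0;
    a1[k + 1] += lambda * -2.0;
    a2[k]     += lambda * 1.0;
  }

  // banded Cholesky A = G G', G lower triangular, bandwidth 2
  std::vector<double> g0(n), g1(n, 0.0), g2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (i >= 2) g2[i] = a2[i - 2] / g0[i - 2];
    if (i >= 1) g1[i] = (a1[i - 1] - (i >= 2 ? g2[i] * g1[i - 1] : 0.0)) / g0[i - 1];
    double d = a0[i] - g1[i] * g1[i] - g2[i] * g2[i];
    if (d <= 0) stop("Whittaker system is not positive definite");
    g0[i] = std::sqrt(d);
  }

  // forward substitution G u = W y
  NumericVector z(n);
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) {
    double b = w[i] * y[i];
    if (i >= 1) b -= g1[i] * u[i - 1];
    if (i >= 2) b -= g2[i] * u[i - 2];
    u[i] = b / g0[i];
  }
  // back substitution G' z = u
  for (int i = n - 1; i >= 0; --i) {
    double b = u[i];
    if (i + 1 < n) b -= g1[i + 1] * z[i + 1];
    if (i + 2 < n) b -= g2[i + 2] * z[i + 2];
    z[i] = b / g0[i];
  }
  return z;
}
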