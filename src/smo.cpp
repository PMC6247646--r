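#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SMO for the binary soft-margin SVM dual on a precomputed kernel, with
// maximal-violating-pair working-set selection and the m - M < tol duality
// stopping rule (Keerthi et al. / LIBSVM WSS1). Deterministic: ties resolve
// to the lowest index.
// [[Rcpp::export(.smo_solve)]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = y.size();
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  if (max_iter <= 0) max_iter = 1000 * n;

  double m = 0.0, M = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    // v_i = y_i - f_i; I_up / I_low by the box and sign constraints
    int i = -1, j = -1;
    m = -HUGE_VAL; M = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    if (L >= H) break;
    double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta > -1e-12) eta = -1e-12;
    const double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj = alpha[j] - y[j] * (Ei - Ej) / eta;
    aj = std::min(std::max(aj, L), H);
    if (std::fabs(aj - alpha[j]) < 1e-14) break;
    const double ai = alpha[i] + y[i] * y[j] * (alpha[j] - aj);
    const double dfi = y[i] * (ai - alpha[i]), dfj = y[j] * (aj - alpha[j]);
    for (int t = 0; t < n; ++t) f[t] += dfi * K(t, i) + dfj * K(t, j);
    alpha[i] = ai; alpha[j] = aj;
  }

  // bias from free support vectors, else the midpoint of the violation gap
  double bsum = 0.0;
  int bcnt = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      bsum += y[t] - f[t];
      ++bcnt;
    }
  }
  const double b = bcnt > 0 ? bsum / bcnt : 0.5 * (m + M);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}
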