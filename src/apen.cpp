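#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pincus approximate entropy Phi_m - Phi_{m+1} with self-matches counted;
// Chebyshev distance between templates of length m and m+1.
// [[Rcpp::export(.apen_core)]]
double apen_core(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;        // templates of length m
  const int nm1 = n - m;           // templates of length m + 1
  std::vector<int> cm(nm, 0), cm1(nm1, 0);
  for (int i = 0; i < nm; ++i) {
    for (int j = 0; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        ++cm[i];
        if (i < nm1 && j < nm1 &&
            std::fabs(x[i + m] - x[j + m]) <= r && d <= r)
          ++cm1[i];
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) phim += std::log((double)cm[i] / nm);
  for (int i = 0; i < nm1; ++i) phim1 += std::log((double)cm1[i] / nm1);
  return phim / nm - phim1 / nm1;
}
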