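#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of unnormalized Gaussian kernels exp(-r^2 / (2 h^2)) centered at
// (tx, ty), evaluated at (px, py); contributions beyond 4 h are dropped.
// [[Rcpp::export(rng = false)]]
NumericVector gauss_field_cpp(NumericVector px, NumericVector py,
                              NumericVector tx, NumericVector ty,
                              double bandwidth) {
  int m = px.size(), n = tx.size();
  NumericVector out(m);
  double inv2h2 = 1.0 / (2.0 * bandwidth * bandwidth);
  double cut2 = 16.0 * bandwidth * bandwidth;
  for (int i = 0; i < m; i++) {
    double s = 0;
    for (int j = 0; j < n; j++) {
      double dx = px[i] - tx[j], dy = py[i] - ty[j];
      double r2 = dx * dx + dy * dy;
      if (r2 <= cut2) s += std::exp(-r2 * inv2h2);
    }
    out[i] = s;
  }
  return out;
}
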