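#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Position of a point relative to a closed ring.
// Returns 0 = outside, 1 = on boundary, 2 = strictly inside.
// Ring may or may not repeat its first vertex; trailing duplicate is ignored.
static int ring_position(double px, double py,
                         const double* rx, const double* ry, int n,
                         double eps = 1e-9) {
  if (n >= 2 && rx[n - 1] == rx[0] && ry[n - 1] == ry[0]) n--;
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double x1 = rx[j], y1 = ry[j], x2 = rx[i], y2 = ry[i];
    // boundary check: point within eps of segment
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy;
    double t = len2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / len2 : 0.0;
    t = std::max(0.0, std::min(1.0, t));
    double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
    if (qx * qx + qy * qy <= eps * eps) return 1;
    // even-odd crossing with half-open rule in y
    if ((y1 > py) != (y2 > py)) {
      double xint = x1 + (py - y1) * dx / dy;
      if (px < xint) inside = !inside;
    }
  }
  return inside ? 2 : 0;
}

//' @noRd
// [[Rcpp::export(rng = false)]]
IntegerVector ring_position_cpp(NumericVector px, NumericVector py,
                                NumericVector rx, NumericVector ry) {
  int np = px.size();
  IntegerVector out(np);
  for (int i = 0; i < np; i++)
    out[i] = ring_position(px[i], py[i], REAL(rx), REAL(ry), rx.size());
  return out;
}

// Scanline crossings of a ring with horizontal line y; returns sorted xs.
static void scan_crossings(double y, const double* rx, const double* ry,
                           int n, std::vector<double>& xs) {
  xs.clear();
  if (n >= 2 && rx[n - 1] == rx[0] && ry[n - 1] == ry[0]) n--;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double x1 = rx[j], y1 = ry[j], x2 = rx[i], y2 = ry[i];
    if ((y1 > y) != (y2 > y))
      xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
  }
  std::sort(xs.begin(), xs.end());
}

// Collect integer pixel centers (x, y) strictly by center-parity inside the
// ring, clipped to [0, w-1] x [0, h-1]. Returns 2-column matrix (x, y).
// [[Rcpp::export(rng = false)]]
IntegerMatrix polygon_pixels_cpp(NumericVector rx, NumericVector ry,
                                 int w, int h) {
  int n = rx.size();
  double ymin = *std::min_element(ry.begin(), ry.end());
  double ymax = *std::max_element(ry.begin(), ry.end());
  int y0 = std::max(0, (int)std::ceil(ymin));
  int y1 = std::min(h - 1, (int)std::floor(ymax));
  std::vector<int> outx, outy;
  std::vector<double> xs;
  for (int y = y0; y <= y1; y++) {
    scan_crossings((double)y, REAL(rx), REAL(ry), n, xs);
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      int xa = std::max(0, (int)std::ceil(xs[s]));
      int xb = std::min(w - 1, (int)std::floor(xs[s + 1]));
      // half-open: pixel exactly on right crossing excluded when xb == xs
      for (int x = xa; x <= xb; x++) { outx.push_back(x); outy.push_back(y); }
    }
  }
  IntegerMatrix out(outx.size(), 2);
  for (size_t i = 0; i < outx.size(); i++) { out(i, 0) = outx[i]; out(i, 1) = outy[i]; }
  return out;
}
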