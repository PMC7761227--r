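#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// simple uniform grid over the joint bounding box, cell side = radius
struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  Grid(const NumericVector& x, const NumericVector& y,
       double xmin, double ymin, double xmax, double ymax, double r)
      : x0(xmin), y0(ymin), cell(r) {
    nx = std::max(1, (int)std::floor((xmax - xmin) / r) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / r) + 1);
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < x.size(); i++) {
      int cx = std::min(nx - 1, std::max(0, (int)std::floor((x[i] - x0) / cell)));
      int cy = std::min(ny - 1, std::max(0, (int)std::floor((y[i] - y0) / cell)));
      bins[(size_t)cy * nx + cx].push_back(i);
    }
  }
};

}  // namespace

// Neighbor counts within Euclidean distance <= r of each focal tumor cell:
// column 1 = tumor neighbors (self excluded), column 2 = lymphocyte
// neighbors. Grid-indexed, but arithmetic identical to the naive scan
// (comparison on squared distances).
// [[Rcpp::export(rng = false)]]
IntegerMatrix neighbor_counts_cpp(NumericVector tx, NumericVector ty,
                                  NumericVector lx, NumericVector ly,
                                  double r) {
  int nt = tx.size(), nl = lx.size();
  IntegerMatrix out(nt, 2);
  if (nt == 0) return out;
  double xmin = tx[0], xmax = tx[0], ymin = ty[0], ymax = ty[0];
  for (int i = 0; i < nt; i++) {
    xmin = std::min(xmin, tx[i]); xmax = std::max(xmax, tx[i]);
    ymin = std::min(ymin, ty[i]); ymax = std::max(ymax, ty[i]);
  }
  for (int i = 0; i < nl; i++) {
    xmin = std::min(xmin, lx[i]); xmax = std::max(xmax, lx[i]);
    ymin = std::min(ymin, ly[i]); ymax = std::max(ymax, ly[i]);
  }
  Grid gt(tx, ty, xmin, ymin, xmax, ymax, r);
  double r2 = r * r;

  std::vector<std::vector<int>>* lbins = nullptr;
  Grid* gl = nullptr;
  if (nl > 0) gl = new Grid(lx, ly, xmin, ymin, xmax, ymax, r);
  (void)lbins;

  for (int i = 0; i < nt; i++) {
    int cx = std::min(gt.nx - 1, std::max(0, (int)std::floor((tx[i] - gt.x0) / gt.cell)));
    int cy = std::min(gt.ny - 1, std::max(0, (int)std::floor((ty[i] - gt.y0) / gt.cell)));
    int ct = 0, cl = 0;
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int bx = cx + dx, by = cy + dy;
        if (bx < 0 || bx >= gt.nx || by < 0 || by >= gt.ny) continue;
        for (int j : gt.bins[(size_t)by * gt.nx + bx]) {
          if (j == i) continue;
          double ddx = tx[j] - tx[i], ddy = ty[j] - ty[i];
          if (ddx * ddx + ddy * ddy <= r2) ct++;
        }
        if (gl) {
          for (int j : gl->bins[(size_t)by * gl->nx + bx]) {
            double ddx = lx[j] - tx[i], ddy = ly[j] - ty[i];
            if (ddx * ddx + ddy * ddy <= r2) cl++;
          }
        }
      }
    out(i, 0) = ct; out(i, 1) = cl;
  }
  delete gl;
  return out;
}

// Mean nearest-neighbor distance within one point set (NA if n < 2).
// [[Rcpp::export(rng = false)]]
double mean_nn_distance_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) return NA_REAL;
  double total = 0;
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / n;
}
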