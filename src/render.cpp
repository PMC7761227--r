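#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "scanfill.h"
using namespace Rcpp;

// Render an H&E-like RGB patch from nucleus polygons into x-major
// matrices (nrow = width, so m(x, y) is pixel (x, y)).
// polys: list of 2-column (x, y) matrices; cls: 1 = tumor, 2 = lymphocyte,
// 3 = other. colors: 3x3 matrix of per-class RGB; bg: length-3 background.
// A coarse (4 px grid, bilinearly interpolated) noise field of sd
// texture_sd modulates each nucleus interior; a single Gaussian field of
// sd noise_sd is added to all three channels (shared luminance noise).
// Uses the R RNG; values clamped to [0, 255].
// [[Rcpp::export]]
List render_patch_cpp(int w, int h, List polys, IntegerVector cls,
                      NumericMatrix colors, NumericVector bg,
                      double noise_sd, double texture_sd) {
  NumericMatrix R(w, h), G(w, h), B(w, h);
  double *rp = REAL(R), *gp = REAL(G), *bp = REAL(B);
  size_t nn = (size_t)w * h;
  for (size_t i = 0; i < nn; i++) { rp[i] = bg[0]; gp[i] = bg[1]; bp[i] = bg[2]; }

  int n = polys.size();
  const int STEP = 4;
  for (int ni = 0; ni < n; ni++) {
    NumericMatrix poly = polys[ni];
    int nv = poly.nrow();
    std::vector<double> rx(nv), ry(nv);
    double xmin = poly(0, 0), xmax = xmin, ymin = poly(0, 1), ymax = ymin;
    for (int i = 0; i < nv; i++) {
      rx[i] = poly(i, 0); ry[i] = poly(i, 1);
      if (rx[i] < xmin) xmin = rx[i]; if (rx[i] > xmax) xmax = rx[i];
      if (ry[i] < ymin) ymin = ry[i]; if (ry[i] > ymax) ymax = ry[i];
    }
    int k = cls[ni] - 1;
    double cr = colors(k, 0), cg = colors(k, 1), cb = colors(k, 2);

    // coarse noise grid over the bounding box
    int gx0 = (int)std::floor(xmin / STEP), gx1 = (int)std::floor(xmax / STEP) + 1;
    int gy0 = (int)std::floor(ymin / STEP), gy1 = (int)std::floor(ymax / STEP) + 1;
    int gw = gx1 - gx0 + 1, gh = gy1 - gy0 + 1;
    std::vector<double> gn((size_t)gw * gh, 0.0);
    if (texture_sd > 0)
      for (size_t i = 0; i < gn.size(); i++) gn[i] = R::rnorm(0.0, texture_sd);

    hespat_fill_polygon(rx.data(), ry.data(), nv, w, h, [&](int x, int y) {
      double t = 0;
      if (texture_sd > 0) {
        double fx = (double)x / STEP - gx0, fy = (double)y / STEP - gy0;
        int ix = (int)fx, iy = (int)fy;
        if (ix >= gw - 1) ix = gw - 2;
        if (iy >= gh - 1) iy = gh - 2;
        double ax = fx - ix, ay = fy - iy;
        t = (1 - ax) * (1 - ay) * gn[(size_t)iy * gw + ix]
          + ax * (1 - ay) * gn[(size_t)iy * gw + ix + 1]
          + (1 - ax) * ay * gn[(size_t)(iy + 1) * gw + ix]
          + ax * ay * gn[(size_t)(iy + 1) * gw + ix + 1];
      }
      size_t off = (size_t)y * w + x;
      rp[off] = cr + t; gp[off] = cg + t; bp[off] = cb + t;
    });
  }

  if (noise_sd > 0) {
    for (size_t i = 0; i < nn; i++) {
      double e = R::rnorm(0.0, noise_sd);
      double r = rp[i] + e, g = gp[i] + e, b = bp[i] + e;
      rp[i] = r < 0 ? 0 : (r > 255 ? 255 : r);
      gp[i] = g < 0 ? 0 : (g > 255 ? 255 : g);
      bp[i] = b < 0 ? 0 : (b > 255 ? 255 : b);
    }
  } else {
    for (size_t i = 0; i < nn; i++) {
      rp[i] = rp[i] < 0 ? 0 : (rp[i] > 255 ? 255 : rp[i]);
      gp[i] = gp[i] < 0 ? 0 : (gp[i] > 255 ? 255 : gp[i]);
      bp[i] = bp[i] < 0 ? 0 : (bp[i] > 255 ? 255 : bp[i]);
    }
  }
  return List::create(_["R"] = R, _["G"] = G, _["B"] = B);
}
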