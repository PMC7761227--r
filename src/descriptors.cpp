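#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include "scanfill.h"
using namespace Rcpp;

// Image matrices throughout this file are in x-major layout: an R matrix
// with nrow = image width, so that m(x, y) addresses pixel (x, y) and
// scanline spans are contiguous in memory.

static const int NG = 32;  // gray levels for histogram entropy and GLCM

static inline int quantize(double v) {
  int g = (int)std::floor(v / 8.0);
  if (g < 0) g = 0;
  if (g > NG - 1) g = NG - 1;
  return g;
}

// R type-7 quantile by selection; reorders v (ascending p calls on the
// same buffer stay correct because nth_element leaves a partial order)
static double quantile7_select(std::vector<double>& v, double p) {
  int n = v.size();
  if (n == 1) return v[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  std::nth_element(v.begin(), v.begin() + lo, v.end());
  double vlo = v[lo];
  if (lo + 1 > n - 1 || h == lo) return vlo;
  double vhi = *std::min_element(v.begin() + lo + 1, v.end());
  return vlo + (h - lo) * (vhi - vlo);
}

struct MomStats { double mean, sd, skew, kurt; };

// population moments; skewness/excess kurtosis defined 0 when sd == 0
static MomStats moments(const std::vector<double>& v) {
  MomStats s = {0, 0, 0, 0};
  int n = v.size();
  if (n == 0) { s.mean = NA_REAL; s.sd = NA_REAL; return s; }
  double m = 0;
  for (double x : v) m += x;
  m /= n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (double x : v) {
    double d = x - m, d2 = d * d;
    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
  }
  m2 /= n; m3 /= n; m4 /= n;
  s.mean = m;
  s.sd = std::sqrt(m2);
  // guard against floating-point dust on effectively constant input
  double eps = 1e-9 * (std::fabs(m) + 1.0);
  if (s.sd <= eps) { s.sd = 0.0; return s; }
  s.skew = m3 / (m2 * s.sd);
  s.kurt = m4 / (m2 * m2) - 3.0;
  return s;
}

// Shannon entropy (bits) of a 32-bin histogram of values in [0, 255]
static double entropy32(const std::vector<double>& v) {
  if (v.empty()) return NA_REAL;
  double h[NG] = {0};
  for (double x : v) h[quantize(x)] += 1.0;
  double e = 0, n = v.size();
  for (int i = 0; i < NG; i++)
    if (h[i] > 0) { double p = h[i] / n; e -= p * std::log2(p); }
  return e;
}

static inline double xlog2(double p) { return p > 0 ? p * std::log2(p) : 0.0; }

// 13 Haralick statistics from a normalized symmetric GLCM, iterating only
// its nonzero entries
static void haralick13(const std::vector<double>& P, double* out) {
  struct Ent { int i, j; double p; };
  std::vector<Ent> nz;
  nz.reserve(256);
  double px[NG] = {0};
  double pxy_sum[2 * NG] = {0};
  double pxy_diff[NG] = {0};
  for (int i = 0; i < NG; i++)
    for (int j = 0; j < NG; j++) {
      double p = P[i * NG + j];
      if (p > 0) {
        nz.push_back({i, j, p});
        px[i] += p;
        pxy_sum[i + j] += p;
        pxy_diff[std::abs(i - j)] += p;
      }
    }
  double mu = 0;
  for (int i = 0; i < NG; i++) mu += i * px[i];
  double sigma2 = 0;
  for (int i = 0; i < NG; i++) sigma2 += (i - mu) * (i - mu) * px[i];

  double lpx[NG];
  for (int i = 0; i < NG; i++) lpx[i] = px[i] > 0 ? std::log2(px[i]) : 0.0;

  double asm_ = 0, contrast = 0, idm = 0, ent = 0, corr_num = 0, hxy1 = 0;
  for (const Ent& e : nz) {
    asm_ += e.p * e.p;
    int dij = e.i - e.j;
    contrast += dij * dij * e.p;
    idm += e.p / (1.0 + dij * dij);
    ent -= e.p * std::log2(e.p);
    corr_num += (double)e.i * e.j * e.p;
    hxy1 -= e.p * (lpx[e.i] + lpx[e.j]);
  }
  double corr = sigma2 > 0 ? (corr_num - mu * mu) / sigma2 : 0.0;

  double sum_avg = 0, sum_ent = 0;
  for (int k = 0; k < 2 * NG; k++) {
    sum_avg += k * pxy_sum[k];
    sum_ent -= xlog2(pxy_sum[k]);
  }
  double sum_var = 0;
  for (int k = 0; k < 2 * NG; k++)
    sum_var += (k - sum_avg) * (k - sum_avg) * pxy_sum[k];

  double diff_avg = 0, diff_ent = 0;
  for (int k = 0; k < NG; k++) diff_avg += k * pxy_diff[k];
  double diff_var = 0;
  for (int k = 0; k < NG; k++) {
    diff_var += (k - diff_avg) * (k - diff_avg) * pxy_diff[k];
    diff_ent -= xlog2(pxy_diff[k]);
  }

  // information measures of correlation; marginals are equal (symmetric
  // GLCM), so HX = HY = -sum px log2 px and HXY2 = 2 HX
  double hx = 0;
  for (int i = 0; i < NG; i++) hx -= px[i] * lpx[i];
  double hxy2 = 2.0 * hx;
  double imc1 = hx > 0 ? (ent - hxy1) / hx : 0.0;
  double e2 = 1.0 - std::exp(-2.0 * (hxy2 - ent));
  double imc2 = e2 > 0 ? std::sqrt(e2) : 0.0;

  out[0] = asm_;      out[1] = contrast;  out[2] = corr;
  out[3] = sigma2;    out[4] = idm;       out[5] = sum_avg;
  out[6] = sum_var;   out[7] = sum_ent;   out[8] = ent;
  out[9] = diff_var;  out[10] = diff_ent; out[11] = imc1; out[12] = imc2;
}

// Direction-averaged normalized symmetric GLCM at a given offset from a
// quantized local grid (-1 = outside mask), written into P (NG*NG).
static bool glcm_offset(const std::vector<int>& grid, int bw, int bh,
                        int d, std::vector<double>& P) {
  std::fill(P.begin(), P.end(), 0.0);
  const int dirs[4][2] = {{d, 0}, {0, d}, {d, d}, {d, -d}};
  std::vector<double> C(NG * NG);
  int ndir = 0;
  for (int k = 0; k < 4; k++) {
    std::fill(C.begin(), C.end(), 0.0);
    int dx = dirs[k][0], dy = dirs[k][1];
    double tot = 0;
    for (int y = 0; y < bh; y++)
      for (int x = 0; x < bw; x++) {
        int a = grid[y * bw + x];
        if (a < 0) continue;
        int x2 = x + dx, y2 = y + dy;
        if (x2 < 0 || x2 >= bw || y2 < 0 || y2 >= bh) continue;
        int b = grid[y2 * bw + x2];
        if (b < 0) continue;
        C[a * NG + b] += 1.0; C[b * NG + a] += 1.0;  // symmetric
        tot += 2.0;
      }
    if (tot > 0) {
      for (int i = 0; i < NG * NG; i++) P[i] += C[i] / tot;
      ndir++;
    }
  }
  if (ndir == 0) return false;
  for (int i = 0; i < NG * NG; i++) P[i] /= ndir;
  return true;
}

// Fused luminance (0.299 R + 0.587 G + 0.114 B), Sobel gradient magnitude
// (clamped borders) and patch-level Otsu threshold of the magnitude
// (256-bin histogram over [0, max]). x-major matrices in and out.
// [[Rcpp::export(rng = false)]]
List luminance_sobel_cpp(NumericMatrix red, NumericMatrix green,
                         NumericMatrix blue) {
  int w = red.nrow(), h = red.ncol();
  NumericMatrix gray(w, h), sob(w, h);
  const double *rp = REAL(red), *gp = REAL(green), *bp = REAL(blue);
  double* gy = REAL(gray);
  size_t nn = (size_t)w * h;
  for (size_t i = 0; i < nn; i++)
    gy[i] = 0.299 * rp[i] + 0.587 * gp[i] + 0.114 * bp[i];

  double* sp = REAL(sob);
  double vmax = 0;
  for (int y = 0; y < h; y++) {
    int ym = std::max(0, y - 1), yp = std::min(h - 1, y + 1);
    const double* c0 = gy + (size_t)ym * w;
    const double* c1 = gy + (size_t)y * w;
    const double* c2 = gy + (size_t)yp * w;
    double* so = sp + (size_t)y * w;
    for (int x = 0; x < w; x++) {
      int xm = std::max(0, x - 1), xp2 = std::min(w - 1, x + 1);
      double gxv = (c0[xp2] + 2 * c1[xp2] + c2[xp2])
                 - (c0[xm] + 2 * c1[xm] + c2[xm]);
      double gyv = (c2[xm] + 2 * c2[x] + c2[xp2])
                 - (c0[xm] + 2 * c0[x] + c0[xp2]);
      double m = std::sqrt(gxv * gxv + gyv * gyv);
      so[x] = m;
      if (m > vmax) vmax = m;
    }
  }

  double thr = 0.0;
  if (vmax > 0) {
    const int NB = 256;
    std::vector<double> hist(NB, 0.0);
    for (size_t i = 0; i < nn; i++) {
      int b = (int)std::floor(sp[i] / vmax * NB);
      if (b > NB - 1) b = NB - 1;
      hist[b] += 1.0;
    }
    double total = (double)nn, sum = 0;
    for (int i = 0; i < NB; i++) sum += i * hist[i];
    double sumB = 0, wB = 0, best = -1, tb = 0;
    for (int i = 0; i < NB; i++) {
      wB += hist[i];
      if (wB == 0) continue;
      double wF = total - wB;
      if (wF == 0) break;
      sumB += i * hist[i];
      double mB = sumB / wB, mF = (sum - sumB) / wF;
      double between = wB * wF * (mB - mF) * (mB - mF);
      if (between > best) { best = between; tb = i; }
    }
    thr = (tb + 0.5) / NB * vmax;
  }
  return List::create(_["gray"] = gray, _["sobel"] = sob, _["otsu"] = thr);
}

// Otsu threshold of an arbitrary value vector (exposed for testing)
// [[Rcpp::export(rng = false)]]
double otsu_threshold_cpp(NumericVector v) {
  int n = v.size();
  if (n == 0) return NA_REAL;
  double vmax = 0;
  for (int i = 0; i < n; i++) if (v[i] > vmax) vmax = v[i];
  if (vmax <= 0) return 0.0;
  const int NB = 256;
  std::vector<double> h(NB, 0.0);
  for (int i = 0; i < n; i++) {
    int b = (int)std::floor(v[i] / vmax * NB);
    if (b > NB - 1) b = NB - 1;
    h[b] += 1.0;
  }
  double total = n, sum = 0;
  for (int i = 0; i < NB; i++) sum += i * h[i];
  double sumB = 0, wB = 0, best = -1, thr = 0;
  for (int i = 0; i < NB; i++) {
    wB += h[i];
    if (wB == 0) continue;
    double wF = total - wB;
    if (wF == 0) break;
    sumB += i * h[i];
    double mB = sumB / wB, mF = (sum - sumB) / wF;
    double between = wB * wF * (mB - mF) * (mB - mF);
    if (between > best) { best = between; thr = i; }
  }
  return (thr + 0.5) / NB * vmax;
}

// Per-nucleus intensity, texture and color descriptors.
// polys: list of 2-column (x, y) polygon matrices; image matrices are
// x-major. Returns n x 65 (7 histogram + 31 texture + 27 color); empty
// masks give all-NA rows, masks under 4 pixels NA texture only.
// [[Rcpp::export(rng = false)]]
NumericMatrix nucleus_descriptors_cpp(List polys, NumericMatrix gray,
                                      NumericMatrix red, NumericMatrix green,
                                      NumericMatrix blue, NumericMatrix sobel,
                                      double otsu) {
  int n = polys.size();
  int w = gray.nrow(), h = gray.ncol();
  NumericMatrix out(n, 65);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> P(NG * NG);
  double har[13];

  for (int ni = 0; ni < n; ni++) {
    NumericMatrix poly = polys[ni];
    int nv = poly.nrow();
    std::vector<double> rx(nv), ry(nv);
    for (int i = 0; i < nv; i++) { rx[i] = poly(i, 0); ry[i] = poly(i, 1); }

    std::vector<int> pxs, pys;
    hespat_fill_polygon(rx.data(), ry.data(), nv, w, h,
                        [&](int x, int y) { pxs.push_back(x); pys.push_back(y); });
    int np = pxs.size();
    if (np == 0) continue;

    std::vector<double> gv(np), rv(np), gvv(np), bv(np), sv(np);
    int xmin = w, xmax = 0, ymin = h, ymax = 0;
    for (int i = 0; i < np; i++) {
      int x = pxs[i], y = pys[i];
      gv[i] = gray(x, y); rv[i] = red(x, y); gvv[i] = green(x, y);
      bv[i] = blue(x, y); sv[i] = sobel(x, y);
      if (x < xmin) xmin = x; if (x > xmax) xmax = x;
      if (y < ymin) ymin = y; if (y > ymax) ymax = y;
    }

    // --- histogram (7)
    MomStats hs = moments(gv);
    std::vector<double> buf(gv);
    out(ni, 0) = hs.mean; out(ni, 1) = hs.sd; out(ni, 2) = hs.skew;
    out(ni, 3) = hs.kurt; out(ni, 4) = entropy32(gv);
    out(ni, 5) = quantile7_select(buf, 0.10);
    out(ni, 6) = quantile7_select(buf, 0.90);

    // --- texture (31): 13 Haralick at offsets 1 and 2, 5 gradient stats
    if (np >= 4) {
      int bw = xmax - xmin + 1, bh = ymax - ymin + 1;
      std::vector<int> grid((size_t)bw * bh, -1);
      for (int i = 0; i < np; i++)
        grid[(size_t)(pys[i] - ymin) * bw + (pxs[i] - xmin)] = quantize(gv[i]);
      for (int oi = 0; oi < 2; oi++) {
        if (glcm_offset(grid, bw, bh, oi + 1, P)) {
          haralick13(P, har);
          for (int j = 0; j < 13; j++) out(ni, 7 + 13 * oi + j) = har[j];
        }
      }
      MomStats gs = moments(sv);
      buf = sv;
      out(ni, 33) = gs.mean; out(ni, 34) = gs.sd; out(ni, 35) = gs.skew;
      out(ni, 36) = quantile7_select(buf, 0.90);
      int above = 0;
      for (int i = 0; i < np; i++) if (sv[i] > otsu) above++;
      out(ni, 37) = (double)above / np;
    }

    // --- color (27): 9 stats per channel
    const std::vector<double>* chans[3] = {&rv, &gvv, &bv};
    for (int c = 0; c < 3; c++) {
      const std::vector<double>& v = *chans[c];
      MomStats cs = moments(v);
      auto mm = std::minmax_element(v.begin(), v.end());
      buf = v;
      int b0 = 38 + 9 * c;
      out(ni, b0 + 0) = cs.mean; out(ni, b0 + 1) = cs.sd;
      out(ni, b0 + 2) = cs.skew; out(ni, b0 + 3) = entropy32(v);
      out(ni, b0 + 4) = quantile7_select(buf, 0.10);
      out(ni, b0 + 5) = quantile7_select(buf, 0.50);
      out(ni, b0 + 6) = quantile7_select(buf, 0.90);
      out(ni, b0 + 7) = *mm.first;
      out(ni, b0 + 8) = *mm.second;
    }
  }
  return out;
}

// Batch polygon morphometry: same 10 descriptors as the R reference
// implementation morphology_features(), for speed on whole specimens.
// Columns: area, perimeter, equivalent_diameter, major_axis, minor_axis,
// eccentricity, solidity, extent, circularity, aspect_ratio.
// [[Rcpp::export(rng = false)]]
NumericMatrix morphology_batch_cpp(List polys) {
  int n = polys.size();
  NumericMatrix out(n, 10);
  for (int ni = 0; ni < n; ni++) {
    NumericMatrix poly = polys[ni];
    int nv = poly.nrow();
    // drop closing duplicate
    if (nv >= 2 && poly(nv - 1, 0) == poly(0, 0) && poly(nv - 1, 1) == poly(0, 1))
      nv--;
    std::vector<double> x(nv), y(nv);
    for (int i = 0; i < nv; i++) { x[i] = poly(i, 0); y[i] = poly(i, 1); }

    double a2 = 0, cx = 0, cy = 0, ixx = 0, iyy = 0, ixy = 0, per = 0;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 0; i < nv; i++) {
      int j = (i + 1) % nv;
      double cr = x[i] * y[j] - x[j] * y[i];
      a2 += cr;
      cx += (x[i] + x[j]) * cr;
      cy += (y[i] + y[j]) * cr;
      ixx += (x[i] * x[i] + x[i] * x[j] + x[j] * x[j]) * cr;
      iyy += (y[i] * y[i] + y[i] * y[j] + y[j] * y[j]) * cr;
      ixy += (x[i] * y[j] + 2 * x[i] * y[i] + 2 * x[j] * y[j] + x[j] * y[i]) * cr;
      per += std::sqrt((x[j] - x[i]) * (x[j] - x[i]) +
                       (y[j] - y[i]) * (y[j] - y[i]));
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    double area = std::fabs(a2) / 2;
    double s = a2 >= 0 ? 1.0 : -1.0;
    cx /= 3 * a2; cy /= 3 * a2;
    double mu20 = s * ixx / 12 / area - cx * cx;
    double mu02 = s * iyy / 12 / area - cy * cy;
    double mu11 = s * ixy / 24 / area - cx * cy;
    double tr = mu20 + mu02, det = mu20 * mu02 - mu11 * mu11;
    double disc = std::sqrt(std::max(0.0, tr * tr / 4 - det));
    double l1 = tr / 2 + disc, l2 = std::max(0.0, tr / 2 - disc);

    // convex hull (monotone chain) for solidity
    std::vector<int> idx(nv);
    for (int i = 0; i < nv; i++) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int i, int j) {
      return x[i] < x[j] || (x[i] == x[j] && y[i] < y[j]);
    });
    auto crossp = [&](int o, int a, int b) {
      return (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o]);
    };
    std::vector<int> hull(2 * nv);
    int k = 0;
    for (int ii = 0; ii < nv; ii++) {
      while (k >= 2 && crossp(hull[k - 2], hull[k - 1], idx[ii]) <= 0) k--;
      hull[k++] = idx[ii];
    }
    int lower = k + 1;
    for (int ii = nv - 2; ii >= 0; ii--) {
      while (k >= lower && crossp(hull[k - 2], hull[k - 1], idx[ii]) <= 0) k--;
      hull[k++] = idx[ii];
    }
    k--;
    double ha2 = 0;
    for (int i = 0; i < k; i++) {
      int j = (i + 1) % k;
      ha2 += x[hull[i]] * y[hull[j]] - x[hull[j]] * y[hull[i]];
    }
    double hull_area = std::fabs(ha2) / 2;

    double major = 4 * std::sqrt(l1), minor = 4 * std::sqrt(l2);
    out(ni, 0) = area;
    out(ni, 1) = per;
    out(ni, 2) = 2 * std::sqrt(area / M_PI);
    out(ni, 3) = major;
    out(ni, 4) = minor;
    out(ni, 5) = l1 > 0 ? std::sqrt(1 - l2 / l1) : 0.0;
    out(ni, 6) = area / hull_area;
    out(ni, 7) = area / ((xmax - xmin) * (ymax - ymin));
    out(ni, 8) = 4 * M_PI * area / (per * per);
    out(ni, 9) = minor > 0 ? major / minor : R_PosInf;
  }
  return out;
}
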