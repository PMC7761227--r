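#ifndef HESPAT_SCANFILL_H
#define HESPAT_SCANFILL_H

#include <vector>
#include <algorithm>
#include <cmath>

// Scanline crossings of a closed ring with the horizontal line at y.
inline void hespat_scan_crossings(double y, const double* rx, const double* ry,
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

// Visit every pixel center (x, y) inside the ring, clipped to the image.
template <typename F>
inline void hespat_fill_polygon(const double* rx, const double* ry, int n,
                                int w, int h, F visit) {
  double ymin = ry[0], ymax = ry[0], dummy;
  (void)dummy;
  for (int i = 1; i < n; i++) {
    if (ry[i] < ymin) ymin = ry[i];
    if (ry[i] > ymax) ymax = ry[i];
  }
  int y0 = std::max(0, (int)std::ceil(ymin));
  int y1 = std::min(h - 1, (int)std::floor(ymax));
  std::vector<double> xs;
  for (int y = y0; y <= y1; y++) {
    hespat_scan_crossings((double)y, rx, ry, n, xs);
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      int xa = std::max(0, (int)std::ceil(xs[s]));
      int xb = std::min(w - 1, (int)std::floor(xs[s + 1]));
      for (int x = xa; x <= xb; x++) visit(x, y);
    }
  }
}

#endif
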