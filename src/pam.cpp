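#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Partition around medoids. Deterministic; all ties broken by lowest
// index. Objective is the sum of distances from each point to its
// nearest medoid. Tiny instances (at most 500 candidate medoid sets) are
// solved exactly by lexicographic enumeration — the optimum trivially
// admits no improving single swap; larger instances use greedy BUILD
// followed by steepest-descent SWAP.
// [[Rcpp::export(rng = false)]]
List pam_cpp(NumericMatrix d, int k) {
  int n = d.nrow();
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < n");

  // number of k-subsets, capped
  double nsets = 1.0;
  for (int i = 0; i < k; i++) nsets = nsets * (n - i) / (i + 1);
  if (nsets <= 500.0) {
    std::vector<int> sel(k), best_sel;
    for (int i = 0; i < k; i++) sel[i] = i;
    double best_obj = R_PosInf;
    for (;;) {
      double obj = 0;
      for (int j = 0; j < n; j++) {
        double b = R_PosInf;
        for (int mi : sel) b = std::min(b, d(mi, j));
        obj += b;
      }
      if (obj < best_obj - 1e-12) { best_obj = obj; best_sel = sel; }
      // next lexicographic k-subset
      int i = k - 1;
      while (i >= 0 && sel[i] == n - k + i) i--;
      if (i < 0) break;
      sel[i]++;
      for (int j = i + 1; j < k; j++) sel[j] = sel[j - 1] + 1;
    }
    IntegerVector labels(n), medoids(k);
    for (int i = 0; i < k; i++) medoids[i] = best_sel[i] + 1;
    for (int j = 0; j < n; j++) {
      double b = R_PosInf;
      int lab = 0;
      for (int i = 0; i < k; i++)
        if (d(best_sel[i], j) < b) { b = d(best_sel[i], j); lab = i; }
      labels[j] = lab + 1;
    }
    return List::create(_["medoids"] = medoids, _["labels"] = labels,
                        _["objective"] = best_obj);
  }

  std::vector<int> med;
  std::vector<bool> is_med(n, false);
  std::vector<double> dn(n, R_PosInf);  // distance to nearest medoid

  // BUILD: first medoid minimizes total distance; then greedy additions
  {
    int best = 0;
    double bestv = R_PosInf;
    for (int i = 0; i < n; i++) {
      double s = 0;
      for (int j = 0; j < n; j++) s += d(i, j);
      if (s < bestv) { bestv = s; best = i; }
    }
    med.push_back(best); is_med[best] = true;
    for (int j = 0; j < n; j++) dn[j] = d(best, j);
  }
  while ((int)med.size() < k) {
    int best = -1;
    double bestgain = -1.0;
    for (int c = 0; c < n; c++) {
      if (is_med[c]) continue;
      double gain = 0;
      for (int j = 0; j < n; j++) {
        double g = dn[j] - d(c, j);
        if (g > 0) gain += g;
      }
      if (gain > bestgain) { bestgain = gain; best = c; }
    }
    med.push_back(best); is_med[best] = true;
    for (int j = 0; j < n; j++) dn[j] = std::min(dn[j], d(best, j));
  }

  auto objective = [&](const std::vector<int>& m) {
    double tot = 0;
    for (int j = 0; j < n; j++) {
      double b = R_PosInf;
      for (int mi : m) b = std::min(b, d(mi, j));
      tot += b;
    }
    return tot;
  };

  // SWAP: steepest descent over all (medoid, non-medoid) exchanges
  double cur = objective(med);
  for (;;) {
    double best_obj = cur;
    int best_mi = -1, best_h = -1;
    for (size_t mi = 0; mi < med.size(); mi++) {
      int old = med[mi];
      for (int hcand = 0; hcand < n; hcand++) {
        if (is_med[hcand]) continue;
        med[mi] = hcand;
        double o = objective(med);
        if (o < best_obj - 1e-12) { best_obj = o; best_mi = mi; best_h = hcand; }
      }
      med[mi] = old;
    }
    if (best_mi < 0) break;
    is_med[med[best_mi]] = false;
    med[best_mi] = best_h;
    is_med[best_h] = true;
    cur = best_obj;
  }

  IntegerVector labels(n), medoids(k);
  for (int i = 0; i < k; i++) medoids[i] = med[i] + 1;
  for (int j = 0; j < n; j++) {
    double b = R_PosInf;
    int lab = 0;
    for (int i = 0; i < k; i++)
      if (d(med[i], j) < b) { b = d(med[i], j); lab = i; }
    labels[j] = lab + 1;
  }
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["objective"] = cur);
}
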