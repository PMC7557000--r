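#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-based label growth inside a binary mask: multi-source Dijkstra on
// the 6-neighbour graph with anisotropic edge weights, i.e. each masked
// voxel is assigned to its geodesically nearest seed. Used to split
// touching endocrine cells after seed detection.

struct QItem {
  double d;
  R_xlen_t idx;
  bool operator<(const QItem &o) const { return d > o.d; } // min-heap
};

// [[Rcpp::export]]
IntegerVector cpp_grow_labels(IntegerVector seeds, IntegerVector mask,
                              IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<double> dist(n, R_PosInf);
  std::priority_queue<QItem> pq;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seeds[s] > 0 && mask[s]) {
      lab[s] = seeds[s];
      dist[s] = 0.0;
      pq.push({0.0, s});
    }
  }
  const int od1[6] = {-1, 1, 0, 0, 0, 0};
  const int od2[6] = {0, 0, -1, 1, 0, 0};
  const int od3[6] = {0, 0, 0, 0, -1, 1};
  const double w[6] = {spacing[0], spacing[0], spacing[1], spacing[1],
                       spacing[2], spacing[2]};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    if (it.d > dist[it.idx]) continue;
    int i = (int)(it.idx % d1);
    int j = (int)((it.idx / d1) % d2);
    int k = (int)(it.idx / ((R_xlen_t)d1 * d2));
    for (int t = 0; t < 6; ++t) {
      int ii = i + od1[t], jj = j + od2[t], kk = k + od3[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
        continue;
      R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
      if (!mask[q]) continue;
      double nd = it.d + w[t];
      if (nd < dist[q]) {
        dist[q] = nd;
        lab[q] = lab[it.idx];
        pq.push({nd, q});
      }
    }
  }
  return lab;
}

// 26-neighbourhood local maxima (>= all neighbours, strictly positive)
// restricted to a mask; returns 1-based voxel indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dim,
                               IntegerVector mask) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<R_xlen_t> hits;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || img[s] <= 0) continue;
    int i = (int)(s % d1);
    int j = (int)((s / d1) % d2);
    int k = (int)(s / ((R_xlen_t)d1 * d2));
    bool is_max = true;
    for (int dz = -1; dz <= 1 && is_max; ++dz)
      for (int dy = -1; dy <= 1 && is_max; ++dy)
        for (int dx = -1; dx <= 1 && is_max; ++dx) {
          if (!dz && !dy && !dx) continue;
          int ii = i + dz, jj = j + dy, kk = k + dx;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            continue;
          R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
          if (img[q] > img[s]) is_max = false;
        }
    if (is_max) hits.push_back(s + 1);
  }
  return IntegerVector(hits.begin(), hits.end());
}
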