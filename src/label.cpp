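#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling, 6 or 26 connectivity, iterative flood
// fill (explicit stack; recursion would overflow on filamentous objects).

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim,
                          int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);

  // neighbour offsets
  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        off1.push_back(dz); off2.push_back(dy); off3.push_back(dx);
      }
  const int noff = (int)off1.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < noff; ++t) {
        int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_objects") = next;
  return lab;
}
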