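#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform with anisotropic voxel spacing,
// Felzenszwalb & Huttenlocher lower-envelope algorithm applied separably
// along each axis. Works on squared distances; physical units throughout.

static const double INF = std::numeric_limits<double>::infinity();

// one 1D pass: f holds current squared distances at n samples spaced s apart
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { // first finite parabola
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue;
    }
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sep <= z[k]) { --k; }
      else {
        ++k; v[k] = q; z[k] = sep; z[k + 1] = INF; break;
      }
    }
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  // init: 0 on foreground, INF elsewhere
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      bool any = false;
      for (int i = 0; i < d1; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d1, spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = d[i];
    }
  // axis 2 (stride d1)
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      bool any = false;
      for (int j = 0; j < d2; ++j) { f[j] = out[base + (R_xlen_t)d1 * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d2, spacing[1]);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)d1 * j] = d[j];
    }
  // axis 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      bool any = false;
      for (int k = 0; k < d3; ++k) { f[k] = out[base + s3 * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d3, spacing[2]);
      for (int k = 0; k < d3; ++k) out[base + s3 * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == INF) ? INF : std::sqrt(out[i]);
  return out;
}
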