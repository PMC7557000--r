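#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterizers for the synthetic phantom. Physical coordinate convention:
// the voxel with R index i along an axis has center (i - 0.5) * spacing,
// i.e. 0-based index idx maps to (idx + 0.5) * spacing.

static inline int lo_idx(double x, double s, int n) {
  int i = (int)std::floor(x / s - 0.5);
  return std::max(0, i);
}
static inline int hi_idx(double x, double s, int n) {
  int i = (int)std::ceil(x / s - 0.5);
  return std::min(n - 1, i);
}

// Axis-aligned-bbox scan; ellipsoid given by center c (z,y,x um), semi-axes
// a (um) and row-major 3x3 rotation R mapping world -> ellipsoid frame.
// Voxels whose center satisfies |R (p - c)| scaled by 1/a <= 1 get `value`.
// [[Rcpp::export]]
void cpp_raster_ellipsoids(IntegerVector grid, IntegerVector dim,
                           NumericVector spacing, NumericMatrix center,
                           NumericMatrix semi, NumericMatrix rot,
                           IntegerVector value) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const int nobj = center.nrow();
  for (int o = 0; o < nobj; ++o) {
    double c1 = center(o, 0), c2 = center(o, 1), c3 = center(o, 2);
    double amax = std::max(semi(o, 0), std::max(semi(o, 1), semi(o, 2)));
    int i0 = lo_idx(c1 - amax, s1, d1), i1 = hi_idx(c1 + amax, s1, d1);
    int j0 = lo_idx(c2 - amax, s2, d2), j1 = hi_idx(c2 + amax, s2, d2);
    int k0 = lo_idx(c3 - amax, s3, d3), k1 = hi_idx(c3 + amax, s3, d3);
    double ia = 1.0 / semi(o, 0), ib = 1.0 / semi(o, 1), ic = 1.0 / semi(o, 2);
    double r00 = rot(3 * o, 0), r01 = rot(3 * o, 1), r02 = rot(3 * o, 2);
    double r10 = rot(3 * o + 1, 0), r11 = rot(3 * o + 1, 1), r12 = rot(3 * o + 1, 2);
    double r20 = rot(3 * o + 2, 0), r21 = rot(3 * o + 2, 1), r22 = rot(3 * o + 2, 2);
    int val = value[o];
    for (int k = k0; k <= k1; ++k) {
      double p3 = (k + 0.5) * s3 - c3;
      for (int j = j0; j <= j1; ++j) {
        double p2 = (j + 0.5) * s2 - c2;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; ++i) {
          double p1 = (i + 0.5) * s1 - c1;
          double q1 = (r00 * p1 + r01 * p2 + r02 * p3) * ia;
          double q2 = (r10 * p1 + r11 * p2 + r12 * p3) * ib;
          double q3 = (r20 * p1 + r21 * p2 + r22 * p3) * ic;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= 1.0) grid[base + i] = val;
        }
      }
    }
  }
}

// Capsules (cylinders with hemispherical caps) from p0 to p1 with given
// radius; voxels inside `forbid` (same shape, nonzero = keep out) are
// skipped, which the phantom uses to guarantee clearance from objects that
// must not be contacted.
// [[Rcpp::export]]
void cpp_raster_capsules(IntegerVector grid, IntegerVector dim,
                         NumericVector spacing, NumericMatrix p0,
                         NumericMatrix p1, NumericVector radius,
                         IntegerVector value, IntegerVector forbid) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const bool has_forbid = forbid.size() == grid.size();
  const int nseg = p0.nrow();
  for (int o = 0; o < nseg; ++o) {
    double a1 = p0(o, 0), a2 = p0(o, 1), a3 = p0(o, 2);
    double b1 = p1(o, 0), b2 = p1(o, 1), b3 = p1(o, 2);
    double r = radius[o];
    double u1 = b1 - a1, u2 = b2 - a2, u3 = b3 - a3;
    double L2 = u1 * u1 + u2 * u2 + u3 * u3;
    int i0 = lo_idx(std::min(a1, b1) - r, s1, d1), i1 = hi_idx(std::max(a1, b1) + r, s1, d1);
    int j0 = lo_idx(std::min(a2, b2) - r, s2, d2), j1 = hi_idx(std::max(a2, b2) + r, s2, d2);
    int k0 = lo_idx(std::min(a3, b3) - r, s3, d3), k1 = hi_idx(std::max(a3, b3) + r, s3, d3);
    int val = value[o];
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double p3 = (k + 0.5) * s3;
      for (int j = j0; j <= j1; ++j) {
        double p2 = (j + 0.5) * s2;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; ++i) {
          double p1 = (i + 0.5) * s1;
          double w1 = p1 - a1, w2 = p2 - a2, w3 = p3 - a3;
          double t = L2 > 0 ? (w1 * u1 + w2 * u2 + w3 * u3) / L2 : 0.0;
          t = std::max(0.0, std::min(1.0, t));
          double q1 = w1 - t * u1, q2 = w2 - t * u2, q3 = w3 - t * u3;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= r2) {
            R_xlen_t s = base + i;
            if (has_forbid && forbid[s]) continue;
            grid[s] = val;
          }
        }
      }
    }
  }
}
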