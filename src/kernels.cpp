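#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// 26-connectivity component labeling of a 3D logical mask.
// Returns an integer volume with components labeled 1..k in order of the
// smallest contained linear (column-major) index, 0 elsewhere.
// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int ix = (int)(v % nx);
      int iy = (int)((v / nx) % ny);
      int iz = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int z = iz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y = iy + dy;
          if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x = ix + dx;
            if (x < 0 || x >= nx) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            R_xlen_t w = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// For each voxel index in `a` (0-based, n x 3), the minimum Euclidean
// distance in mm to any voxel index in `b`, given voxel spacing in mm.
// [[Rcpp::export(name = ".min_distances_mm")]]
NumericVector min_distances_mm(IntegerMatrix a, IntegerMatrix b,
                               NumericVector spacing) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0) * sx, ay = a(i, 1) * sy, az = a(i, 2) * sz;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0) * sx;
      const double dy = ay - b(j, 1) * sy;
      const double dz = az - b(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline double bilinear_xy(const double *v, int nx, int ny,
                                 R_xlen_t zoff, double fx, double fy) {
  // fx, fy are fractional 0-based voxel coordinates within one z-slice;
  // outside the slice the field is taken as 0.
  if (fx < -1.0 || fx > nx || fy < -1.0 || fy > ny) return 0.0;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
  double wx = fx - x0, wy = fy - y0;
  double acc = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    int y = y0 + dy;
    if (y < 0 || y >= ny) continue;
    double wyv = dy ? wy : 1.0 - wy;
    if (wyv == 0.0) continue;
    for (int dx = 0; dx <= 1; ++dx) {
      int x = x0 + dx;
      if (x < 0 || x >= nx) continue;
      double wxv = dx ? wx : 1.0 - wx;
      if (wxv == 0.0) continue;
      acc += wxv * wyv * v[zoff + (R_xlen_t)x + (R_xlen_t)nx * y];
    }
  }
  return acc;
}

// First-order attenuation-bias field: for each voxel, the mean over
// n_angles evenly spaced in-plane line directions of exp(line integral of
// dmu along the full-grid line through the voxel).  dmu is in cm^-1 and the
// grid spacing in mm, so path lengths are converted by 1/10.
//
// All voxels on one full-grid line share the integral, so integrals are
// evaluated once per (angle, slice, perpendicular offset) on an offset grid
// with resolution `step` mm and linearly interpolated per voxel.
// [[Rcpp::export(name = ".ray_bias_field")]]
NumericVector ray_bias_field(NumericVector dmu, IntegerVector dims,
                             NumericVector spacing, int n_angles,
                             double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  const double dx = spacing[0], dy = spacing[1];
  NumericVector out(n);
  const double *v = REAL(dmu);

  // physical in-plane coordinates relative to the first voxel center
  const double xmax = (nx - 1) * dx, ymax = (ny - 1) * dy;

  std::vector<double> integ;   // per-offset line integrals
  std::vector<double> acc(n, 0.0);

  for (int k = 0; k < n_angles; ++k) {
    const double th = M_PI * k / n_angles;
    const double cx = std::cos(th), sx_ = std::sin(th);   // line direction
    const double px = -sx_, py = cx;                      // perpendicular
    // offset range across the slice rectangle corners
    double umin = R_PosInf, umax = R_NegInf;
    double tmin = R_PosInf, tmax = R_NegInf;
    const double corners[4][2] = {
      {0.0, 0.0}, {xmax, 0.0}, {0.0, ymax}, {xmax, ymax}};
    for (int c = 0; c < 4; ++c) {
      const double u = px * corners[c][0] + py * corners[c][1];
      const double t = cx * corners[c][0] + sx_ * corners[c][1];
      if (u < umin) umin = u;
      if (u > umax) umax = u;
      if (t < tmin) tmin = t;
      if (t > tmax) tmax = t;
    }
    const int nu = (int)std::ceil((umax - umin) / step) + 2;
    const int nt = (int)std::ceil((tmax - tmin) / step) + 2;
    integ.assign((size_t)nu, 0.0);

    for (int iz = 0; iz < nz; ++iz) {
      const R_xlen_t zoff = nxy * iz;
      for (int ju = 0; ju < nu; ++ju) {
        const double u = umin + ju * step;
        double s = 0.0;
        for (int jt = 0; jt < nt; ++jt) {
          const double t = tmin + jt * step;
          const double X = u * px + t * cx;   // mm, relative to voxel (0,0)
          const double Y = u * py + t * sx_;
          s += bilinear_xy(v, nx, ny, zoff, X / dx, Y / dy);
        }
        integ[ju] = s * step * 0.1;   // mm -> cm
      }
      // per-voxel interpolation of exp(integral)
      for (int iy = 0; iy < ny; ++iy) {
        const double yph = iy * dy;
        const double base = px * 0.0 + py * yph;
        for (int ix = 0; ix < nx; ++ix) {
          const double u = base + px * (ix * dx);
          double fu = (u - umin) / step;
          int j0 = (int)std::floor(fu);
          if (j0 < 0) j0 = 0;
          if (j0 > nu - 2) j0 = nu - 2;
          const double w = fu - j0;
          const double I = (1.0 - w) * integ[j0] + w * integ[j0 + 1];
          acc[zoff + (R_xlen_t)ix + (R_xlen_t)nx * iy] += std::exp(I);
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = acc[i] / n_angles;
  out.attr("dim") = dims;
  return out;
}
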