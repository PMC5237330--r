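#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shared sampling helpers. Volumes are column-major x-fastest arrays; voxel
// (i,j,k) (0-based) sits at physical position origin + (i,j,k)*spacing.

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
  Grid(const IntegerVector& dims, const NumericVector& spacing,
       const NumericVector& origin)
      : nx(dims[0]), ny(dims[1]), nz(dims[2]), sx(spacing[0]), sy(spacing[1]),
        sz(spacing[2]), ox(origin[0]), oy(origin[1]), oz(origin[2]) {}
};

static inline double sample_nn(const double* v, const Grid& g, double x,
                               double y, double z, double fill) {
  int i = (int)std::lround((x - g.ox) / g.sx);
  int j = (int)std::lround((y - g.oy) / g.sy);
  int k = (int)std::lround((z - g.oz) / g.sz);
  if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
    return fill;
  return v[(size_t)k * g.nx * g.ny + (size_t)j * g.nx + i];
}

static inline double sample_lin(const double* v, const Grid& g, double x,
                                double y, double z, double fill) {
  double fi = (x - g.ox) / g.sx, fj = (y - g.oy) / g.sy,
         fk = (z - g.oz) / g.sz;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
      k0 = (int)std::floor(fk);
  double di = fi - i0, dj = fj - j0, dk = fk - k0;
  if (i0 >= 0 && j0 >= 0 && k0 >= 0 && i0 + 1 < g.nx && j0 + 1 < g.ny &&
      k0 + 1 < g.nz) {
    // fully interior: direct 8-corner gather
    const size_t sxy = (size_t)g.nx * g.ny;
    const double* p = v + (size_t)k0 * sxy + (size_t)j0 * g.nx + i0;
    double c00 = p[0] + di * (p[1] - p[0]);
    double c10 = p[g.nx] + di * (p[g.nx + 1] - p[g.nx]);
    double c01 = p[sxy] + di * (p[sxy + 1] - p[sxy]);
    double c11 = p[sxy + g.nx] + di * (p[sxy + g.nx + 1] - p[sxy + g.nx]);
    double c0 = c00 + dj * (c10 - c00);
    double c1 = c01 + dj * (c11 - c01);
    return c0 + dk * (c1 - c0);
  }
  if (i0 < -1 || j0 < -1 || k0 < -1 || i0 >= g.nx || j0 >= g.ny || k0 >= g.nz)
    return fill;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int ii = i0 + dx, jj = j0 + dy, kk = k0 + dz;
        double w = (dx ? di : 1 - di) * (dy ? dj : 1 - dj) * (dz ? dk : 1 - dk);
        double val = (ii < 0 || jj < 0 || kk < 0 || ii >= g.nx || jj >= g.ny ||
                      kk >= g.nz)
                         ? fill
                         : v[(size_t)kk * g.nx * g.ny + (size_t)jj * g.nx + ii];
        acc += w * val;
      }
  return acc;
}

// physical-space bounding box of the non-negligible support of `v`, padded
// by one voxel; used to skip interpolation where both images vanish
struct SupportBox {
  double x0, x1, y0, y1, z0, z1;
  bool empty;
};

static SupportBox support_box(const double* v, const Grid& g, double tol) {
  int ilo = g.nx, ihi = -1, jlo = g.ny, jhi = -1, klo = g.nz, khi = -1;
  size_t idx = 0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i, ++idx) {
        if (std::fabs(v[idx]) > tol) {
          if (i < ilo) ilo = i;
          if (i > ihi) ihi = i;
          if (j < jlo) jlo = j;
          if (j > jhi) jhi = j;
          if (k < klo) klo = k;
          if (k > khi) khi = k;
        }
      }
  SupportBox b;
  b.empty = ihi < 0;
  b.x0 = g.ox + (ilo - 1.5) * g.sx; b.x1 = g.ox + (ihi + 1.5) * g.sx;
  b.y0 = g.oy + (jlo - 1.5) * g.sy; b.y1 = g.oy + (jhi + 1.5) * g.sy;
  b.z0 = g.oz + (klo - 1.5) * g.sz; b.z1 = g.oz + (khi + 1.5) * g.sz;
  return b;
}

// Pull-back resampling under a physical-space map given by a 4x4 matrix
// `inv` (the INVERSE of the forward transform): out(y) = in(inv %*% y).
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix inv, bool nearest,
                                  double fill) {
  Grid g(dims, spacing, origin);
  NumericVector out((size_t)g.nx * g.ny * g.nz);
  const double* v = vol.begin();
  const double a00 = inv(0, 0), a01 = inv(0, 1), a02 = inv(0, 2),
               a03 = inv(0, 3);
  const double a10 = inv(1, 0), a11 = inv(1, 1), a12 = inv(1, 2),
               a13 = inv(1, 3);
  const double a20 = inv(2, 0), a21 = inv(2, 1), a22 = inv(2, 2),
               a23 = inv(2, 3);
  size_t idx = 0;
  for (int k = 0; k < g.nz; ++k) {
    double zc = g.oz + k * g.sz;
    for (int j = 0; j < g.ny; ++j) {
      double yc = g.oy + j * g.sy;
      // incremental stepping along x
      double xs = a00 * g.ox + a01 * yc + a02 * zc + a03;
      double ys = a10 * g.ox + a11 * yc + a12 * zc + a13;
      double zs = a20 * g.ox + a21 * yc + a22 * zc + a23;
      const double dxs = a00 * g.sx, dys = a10 * g.sx, dzs = a20 * g.sx;
      for (int i = 0; i < g.nx; ++i, ++idx, xs += dxs, ys += dys, zs += dzs) {
        out[idx] = nearest ? sample_nn(v, g, xs, ys, zs, fill)
                           : sample_lin(v, g, xs, ys, zs, fill);
      }
    }
  }
  return out;
}

// SSD between `fixed` and `moving` pulled back through `inv`, evaluated with
// trilinear interpolation (the registration cost). Voxels where the fixed
// image vanishes and the sample point falls outside the moving support box
// contribute nothing and are skipped.
// [[Rcpp::export(name = ".ssd_affine_cpp")]]
double ssd_affine_cpp(NumericVector moving, NumericVector fixed,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector origin, NumericMatrix inv) {
  Grid g(dims, spacing, origin);
  const double* mv = moving.begin();
  const double* fx = fixed.begin();
  SupportBox box = support_box(mv, g, 1e-9);
  const double a00 = inv(0, 0), a01 = inv(0, 1), a02 = inv(0, 2),
               a03 = inv(0, 3);
  const double a10 = inv(1, 0), a11 = inv(1, 1), a12 = inv(1, 2),
               a13 = inv(1, 3);
  const double a20 = inv(2, 0), a21 = inv(2, 1), a22 = inv(2, 2),
               a23 = inv(2, 3);
  double acc = 0.0;
  size_t idx = 0;
  for (int k = 0; k < g.nz; ++k) {
    double zc = g.oz + k * g.sz;
    for (int j = 0; j < g.ny; ++j) {
      double yc = g.oy + j * g.sy;
      double xs = a00 * g.ox + a01 * yc + a02 * zc + a03;
      double ys = a10 * g.ox + a11 * yc + a12 * zc + a13;
      double zs = a20 * g.ox + a21 * yc + a22 * zc + a23;
      const double dxs = a00 * g.sx, dys = a10 * g.sx, dzs = a20 * g.sx;
      for (int i = 0; i < g.nx; ++i, ++idx, xs += dxs, ys += dys, zs += dzs) {
        double f = fx[idx];
        if (f == 0.0 && (box.empty || xs < box.x0 || xs > box.x1 ||
                         ys < box.y0 || ys > box.y1 || zs < box.z0 ||
                         zs > box.z1))
          continue;
        double d = f - sample_lin(mv, g, xs, ys, zs, 0.0);
        acc += d * d;
      }
    }
  }
  return acc;
}

// Pull-back warp by a dense displacement field (mm): out(y) = in(y + u(y)).
// [[Rcpp::export(name = ".warp_field_cpp")]]
NumericVector warp_field_cpp(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector ux, NumericVector uy,
                             NumericVector uz, bool nearest, double fill) {
  Grid g(dims, spacing, origin);
  NumericVector out((size_t)g.nx * g.ny * g.nz);
  const double* v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < g.nz; ++k) {
    double zc = g.oz + k * g.sz;
    for (int j = 0; j < g.ny; ++j) {
      double yc = g.oy + j * g.sy;
      for (int i = 0; i < g.nx; ++i, ++idx) {
        double xc = g.ox + i * g.sx;
        double xs = xc + ux[idx], ys = yc + uy[idx], zs = zc + uz[idx];
        out[idx] = nearest ? sample_nn(v, g, xs, ys, zs, fill)
                           : sample_lin(v, g, xs, ys, zs, fill);
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxel units; FIR kernel
// truncated at 3 sigma, normalized; borders renormalize over the in-range
// taps only.
// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double wsum = 0.0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      wsum += w[t + r];
    }
    for (int t = 0; t <= 2 * r; ++t) w[t] /= wsum; // interior normalization
    int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
    size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx
                                               : (size_t)nx * ny);
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    for (int c2 = 0; c2 < n2; ++c2) {
      for (int c1 = 0; c1 < n1; ++c1) {
        size_t base;
        if (axis == 0) base = (size_t)c2 * nx * ny + (size_t)c1 * nx;
        else if (axis == 1) base = (size_t)c2 * nx * ny + c1;
        else base = (size_t)c2 * nx + c1;
        // border region: renormalize over in-range taps
        int lo_end = std::min(r, n);
        for (int q = 0; q < lo_end; ++q) {
          double acc = 0.0, norm = 0.0;
          int lo = -q, hi = std::min(r, n - 1 - q);
          const double* src = &a[base + (size_t)q * stride];
          for (int t = lo; t <= hi; ++t) {
            acc += w[t + r] * src[(long)t * (long)stride];
            norm += w[t + r];
          }
          b[base + (size_t)q * stride] = acc / norm;
        }
        // interior: fixed normalized kernel
        for (int q = r; q < n - r; ++q) {
          double acc = 0.0;
          const double* src = &a[base + (size_t)q * stride];
          for (int t = -r; t <= r; ++t)
            acc += w[t + r] * src[(long)t * (long)stride];
          b[base + (size_t)q * stride] = acc;
        }
        // trailing border
        for (int q = std::max(n - r, lo_end); q < n; ++q) {
          double acc = 0.0, norm = 0.0;
          int lo = std::max(-r, -q), hi = n - 1 - q;
          const double* src = &a[base + (size_t)q * stride];
          for (int t = lo; t <= hi; ++t) {
            acc += w[t + r] * src[(long)t * (long)stride];
            norm += w[t + r];
          }
          b[base + (size_t)q * stride] = acc / norm;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
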