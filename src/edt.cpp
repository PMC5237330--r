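#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable per axis with anisotropic voxel spacing. Distances are between
// voxel centres, in physical (mm) units. Empty-source voxels carry a large
// finite sentinel so the lower-envelope arithmetic stays NaN-free.

static const double BIG = 1e15;

// 1-D squared distance transform on samples at positions i*w, i = 0..n-1.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = (((f[q] + (double)q * q * w2) -
                 (f[v[k]] + (double)v[k] * v[k] * w2)) /
                (2.0 * w2 * (q - v[k])));
    while (s <= z[k]) {
      --k;
      s = (((f[q] + (double)q * q * w2) -
            (f[v[k]] + (double)v[k] * v[k] * w2)) /
           (2.0 * w2 * (q - v[k])));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) * w2 + f[v[k]];
  }
}

static void edt3_inplace(std::vector<double>& g, const IntegerVector& dims,
                         const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = &g[(size_t)k * nx * ny + (size_t)j * nx];
      dt1d(row, d.data(), nx, spacing[0], v, z);
      std::copy(d.begin(), d.begin() + nx, row);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = g[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j)
        g[(size_t)k * nx * ny + (size_t)j * nx + i] = d[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = g[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k)
        g[(size_t)k * nx * ny + (size_t)j * nx + i] = d[k];
    }
}

// Euclidean distance (mm) from every voxel centre to the nearest voxel
// centre with mask != 0; 0 on the mask itself, Inf if the mask is empty.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  size_t n = mask.size();
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] != 0 ? 0.0 : BIG;
  edt3_inplace(g, dims, spacing);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// Two-sided signed distance: +dist to nearest foreground centre outside,
// -dist to nearest background centre inside.
// [[Rcpp::export(name = ".signed_distance_cpp")]]
NumericVector signed_distance_cpp(IntegerVector mask, IntegerVector dims,
                                  NumericVector spacing) {
  size_t n = mask.size();
  std::vector<double> gf(n), gb(n);
  for (size_t i = 0; i < n; ++i) {
    gf[i] = mask[i] != 0 ? 0.0 : BIG;
    gb[i] = mask[i] != 0 ? BIG : 0.0;
  }
  edt3_inplace(gf, dims, spacing);
  edt3_inplace(gb, dims, spacing);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i)
    out[i] = mask[i] != 0 ? -std::sqrt(gb[i]) : std::sqrt(gf[i]);
  return out;
}
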