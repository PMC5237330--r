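#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector sigma_vox);
NumericVector warp_field_cpp(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector ux, NumericVector uy,
                             NumericVector uz, bool nearest, double fill);

// central-difference gradient along one axis, in 1/mm units
static void gradient_axis(const std::vector<double>& v, std::vector<double>& g,
                          int nx, int ny, int nz, int axis, double sp) {
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int q = axis == 0 ? i : (axis == 1 ? j : k);
        double hi = (q + 1 < n) ? v[idx + stride] : v[idx];
        double lo = (q - 1 >= 0) ? v[idx - stride] : v[idx];
        double den = ((q + 1 < n) && (q - 1 >= 0)) ? 2.0 * sp : sp;
        g[idx] = (hi - lo) / den;
      }
}

// Symmetric-forces demons with Gaussian field regularization. `fixedv` and
// `movingv` are pre-smoothed float images; the returned displacement (mm)
// maps a fixed-frame point to the location where `moving` is sampled
// (pull-back convention). The field with the lowest SSD seen over the
// iterations is returned, so the result never degrades below the identity.
// [[Rcpp::export(name = ".demons_cpp")]]
List demons_cpp(NumericVector movingv, NumericVector fixedv,
                IntegerVector dims, NumericVector spacing,
                NumericVector origin, int iterations, double sigma_field_vox,
                double sigma_fluid_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> F(fixedv.begin(), fixedv.end());
  std::vector<double> gfx(n), gfy(n), gfz(n), gmx(n), gmy(n), gmz(n);
  gradient_axis(F, gfx, nx, ny, nz, 0, spacing[0]);
  gradient_axis(F, gfy, nx, ny, nz, 1, spacing[1]);
  gradient_axis(F, gfz, nx, ny, nz, 2, spacing[2]);
  NumericVector ux(n), uy(n), uz(n);
  NumericVector bux(n), buy(n), buz(n);
  NumericVector sig(3);
  sig[0] = sig[1] = sig[2] = sigma_field_vox;
  double init_ssd = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double d = fixedv[i] - movingv[i];
    init_ssd += d * d;
  }
  double best_ssd = init_ssd;
  int done = 0;
  for (int it = 0; it < iterations; ++it) {
    NumericVector Mw = warp_field_cpp(movingv, dims, spacing, origin, ux, uy,
                                      uz, false, 0.0);
    double ssd = 0.0;
    for (size_t i = 0; i < n; ++i) {
      double d = fixedv[i] - Mw[i];
      ssd += d * d;
    }
    if (ssd < best_ssd) {
      best_ssd = ssd;
      std::copy(ux.begin(), ux.end(), bux.begin());
      std::copy(uy.begin(), uy.end(), buy.begin());
      std::copy(uz.begin(), uz.end(), buz.begin());
    }
    std::vector<double> Mwv(Mw.begin(), Mw.end());
    gradient_axis(Mwv, gmx, nx, ny, nz, 0, spacing[0]);
    gradient_axis(Mwv, gmy, nx, ny, nz, 1, spacing[1]);
    gradient_axis(Mwv, gmz, nx, ny, nz, 2, spacing[2]);
    NumericVector dx(n), dy(n), dz(n);
    for (size_t i = 0; i < n; ++i) {
      double diff = Mw[i] - F[i];
      double jx = 0.5 * (gfx[i] + gmx[i]);
      double jy = 0.5 * (gfy[i] + gmy[i]);
      double jz = 0.5 * (gfz[i] + gmz[i]);
      double den = jx * jx + jy * jy + jz * jz + diff * diff;
      if (den > 1e-12) {
        // Gauss-Newton step on (M(y+u) - F(y))^2: du = (F - Mw) J / den
        double a = -diff / den;
        dx[i] = a * jx;
        dy[i] = a * jy;
        dz[i] = a * jz;
      }
    }
    if (sigma_fluid_vox > 0) {
      NumericVector sigf(3);
      sigf[0] = sigf[1] = sigf[2] = sigma_fluid_vox;
      dx = gauss_smooth_cpp(dx, dims, sigf);
      dy = gauss_smooth_cpp(dy, dims, sigf);
      dz = gauss_smooth_cpp(dz, dims, sigf);
    }
    for (size_t i = 0; i < n; ++i) {
      ux[i] += dx[i];
      uy[i] += dy[i];
      uz[i] += dz[i];
    }
    if (sigma_field_vox > 0) {
      ux = gauss_smooth_cpp(ux, dims, sig);
      uy = gauss_smooth_cpp(uy, dims, sig);
      uz = gauss_smooth_cpp(uz, dims, sig);
    }
    done = it + 1;
  }
  // final candidate
  NumericVector Mw = warp_field_cpp(movingv, dims, spacing, origin, ux, uy,
                                    uz, false, 0.0);
  double ssd = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double d = fixedv[i] - Mw[i];
    ssd += d * d;
  }
  if (ssd < best_ssd) {
    best_ssd = ssd;
    bux = ux; buy = uy; buz = uz;
  }
  return List::create(_["ux"] = bux, _["uy"] = buy, _["uz"] = buz,
                      _["initial_ssd"] = init_ssd, _["final_ssd"] = best_ssd,
                      _["iterations"] = done);
}
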