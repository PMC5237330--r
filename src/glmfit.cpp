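#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Locally weighted logistic fits of voxel coverage on the mean signed
// distance, evaluated at every voxel of the transition band. The spatial
// tricube weights are exact; the predictor (mean signed distance) is
// discretized into `nbins` bins so that each Newton solve works on binned
// sufficient statistics instead of revisiting every neighbour per iteration.

static inline double tricube_w(double u) {
  if (u < 0) u = -u;
  if (u > 1.0) return 0.0;
  double a = 1.0 - u * u * u;
  return (70.0 / 81.0) * a * a * a;
}

static inline double logistic(double eta) {
  if (eta > 30.0) eta = 30.0;
  if (eta < -30.0) eta = -30.0;
  return 1.0 / (1.0 + std::exp(-eta));
}

// weighted Bernoulli loglikelihood on bins
static double binned_loglik(const std::vector<double>& A,
                            const std::vector<double>& C,
                            const std::vector<double>& tc, int nb, int p,
                            const double* beta, int nsh) {
  double ll = 0.0;
  for (int b = 0; b < nb; ++b) {
    if (A[b] <= 0) continue;
    double t = tc[b];
    double eta = beta[0] + (p > 1 ? beta[1] * t : 0.0) +
                 (p > 2 ? beta[2] * t * t : 0.0);
    double mu = logistic(eta);
    if (mu < 1e-12) mu = 1e-12;
    if (mu > 1 - 1e-12) mu = 1 - 1e-12;
    ll += C[b] * std::log(mu) + (nsh * A[b] - C[b]) * std::log(1.0 - mu);
  }
  return ll;
}

// solve the p x p system H x = g in place (p <= 3), tiny ridge for safety
static bool solve_small(double H[3][3], double g[3], double x[3], int p) {
  double a[3][4];
  double tr = 0.0;
  for (int i = 0; i < p; ++i) tr += H[i][i];
  double ridge = 1e-10 * (tr > 0 ? tr : 1.0);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) a[i][j] = H[i][j] + (i == j ? ridge : 0.0);
    a[i][p] = g[i];
  }
  for (int c = 0; c < p; ++c) {
    int piv = c;
    for (int r = c + 1; r < p; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    if (std::fabs(a[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = 0; j <= p; ++j) std::swap(a[c][j], a[piv][j]);
    for (int r = 0; r < p; ++r) {
      if (r == c) continue;
      double f = a[r][c] / a[c][c];
      for (int j = c; j <= p; ++j) a[r][j] -= f * a[c][j];
    }
  }
  for (int i = 0; i < p; ++i) x[i] = a[i][p] / a[i][i];
  return true;
}

// [[Rcpp::export(name = ".glm_band_fit_cpp")]]
List glm_band_fit_cpp(NumericVector dstar, IntegerVector cov, int nsh,
                      IntegerVector dims, NumericVector spacing,
                      double band_halfwidth, double bandwidth_mm, double span,
                      int order, double eps, int nbins, int max_iter,
                      double tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const size_t n = (size_t)nx * ny * nz;
  const int p = order + 1;

  // collect band voxels
  std::vector<double> px, py, pz, pd;
  std::vector<int> pc;
  std::vector<size_t> pidx;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double d = dstar[idx];
        if (std::fabs(d) <= band_halfwidth) {
          px.push_back(i * sx);
          py.push_back(j * sy);
          pz.push_back(k * sz);
          pd.push_back(d);
          pc.push_back(cov[idx]);
          pidx.push_back(idx);
        }
      }
  const size_t B = pd.size();

  NumericVector prob(n);
  for (size_t i = 0; i < n; ++i)
    prob[i] = dstar[i] < -band_halfwidth ? 1.0 - eps : eps;
  if (B == 0)
    return List::create(_["prob"] = prob, _["n_band"] = 0,
                        _["n_converged"] = 0, _["n_shortcut"] = 0,
                        _["mean_bandwidth"] = NA_REAL);

  // predictor bins over the band's distance range
  double dmin = *std::min_element(pd.begin(), pd.end());
  double dmax = *std::max_element(pd.begin(), pd.end());
  double drange = dmax - dmin;
  if (drange <= 0) drange = 1.0;
  const double scale = band_halfwidth > 0 ? band_halfwidth : 1.0;
  std::vector<int> pbin(B);
  std::vector<double> tcent(nbins);
  for (int b = 0; b < nbins; ++b)
    tcent[b] = (dmin + (b + 0.5) / nbins * drange) / scale;
  for (size_t jj = 0; jj < B; ++jj) {
    int b = (int)((pd[jj] - dmin) / drange * nbins);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    pbin[jj] = b;
  }

  std::vector<double> d2(B), A(nbins), C(nbins);
  int n_conv = 0, n_short = 0;
  double h_sum = 0.0;
  // span quantile estimated on a deterministic stride subsample: the
  // bandwidth is a distance quantile, stable under thinning
  size_t stride_s = B > 4096 ? (B + 4095) / 4096 : 1;
  size_t Bs = (B + stride_s - 1) / stride_s;
  std::vector<double> d2s(Bs);
  size_t kth = (size_t)std::ceil(span * (double)Bs);
  if (kth < 2) kth = 2;
  if (kth > Bs) kth = Bs;

  for (size_t v = 0; v < B; ++v) {
    double x0 = px[v], y0 = py[v], z0 = pz[v];
    for (size_t jj = 0; jj < B; ++jj) {
      double dx = px[jj] - x0, dy = py[jj] - y0, dz = pz[jj] - z0;
      d2[jj] = dx * dx + dy * dy + dz * dz;
    }
    double h;
    if (bandwidth_mm > 0) {
      h = bandwidth_mm;
    } else {
      size_t m = 0;
      for (size_t jj = 0; jj < B; jj += stride_s) d2s[m++] = d2[jj];
      std::nth_element(d2s.begin(), d2s.begin() + (kth - 1),
                       d2s.begin() + m);
      h = std::sqrt(d2s[kth - 1]);
      if (h <= 0) h = std::max(sx, std::max(sy, sz));
    }
    h_sum += h;
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    const double h2 = h * h;
    for (size_t jj = 0; jj < B; ++jj) {
      if (d2[jj] >= h2) continue;
      double w = tricube_w(std::sqrt(d2[jj]) / h);
      A[pbin[jj]] += w;
      C[pbin[jj]] += w * pc[jj];
    }
    double sumA = 0.0, sumC = 0.0;
    for (int b = 0; b < nbins; ++b) { sumA += A[b]; sumC += C[b]; }
    double t0 = pd[v] / scale;
    double pv;
    if (sumA <= 0 || sumC <= 1e-12) {
      pv = eps;
      ++n_short;
    } else if (sumC >= nsh * sumA - 1e-12) {
      pv = 1.0 - eps;
      ++n_short;
    } else {
      double beta[3] = {0.0, 0.0, 0.0};
      double pbar = sumC / (nsh * sumA);
      if (pbar < 1e-3) pbar = 1e-3;
      if (pbar > 1 - 1e-3) pbar = 1 - 1e-3;
      beta[0] = std::log(pbar / (1.0 - pbar));
      double ll = binned_loglik(A, C, tcent, nbins, p, beta, nsh);
      bool conv = false;
      for (int it = 0; it < max_iter; ++it) {
        double g[3] = {0, 0, 0};
        double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
        for (int b = 0; b < nbins; ++b) {
          if (A[b] <= 0) continue;
          double t = tcent[b];
          double vb[3] = {1.0, t, t * t};
          double eta = beta[0];
          for (int q = 1; q < p; ++q) eta += beta[q] * vb[q];
          double mu = logistic(eta);
          double r = C[b] - nsh * A[b] * mu;
          double wq = nsh * A[b] * mu * (1.0 - mu);
          for (int q = 0; q < p; ++q) {
            g[q] += r * vb[q];
            for (int s = 0; s <= q; ++s) H[q][s] += wq * vb[q] * vb[s];
          }
        }
        for (int q = 0; q < p; ++q)
          for (int s = q + 1; s < p; ++s) H[q][s] = H[s][q];
        double step[3];
        if (!solve_small(H, g, step, p)) break;
        double smax = 0.0;
        for (int q = 0; q < p; ++q) smax = std::max(smax, std::fabs(step[q]));
        // damped update with halving
        double f = 1.0;
        double newbeta[3];
        double newll = -1e300;
        for (int half = 0; half < 20; ++half) {
          for (int q = 0; q < p; ++q) newbeta[q] = beta[q] + f * step[q];
          newll = binned_loglik(A, C, tcent, nbins, p, newbeta, nsh);
          if (newll >= ll - 1e-12) break;
          f *= 0.5;
        }
        for (int q = 0; q < p; ++q) beta[q] = newbeta[q];
        if (newll < ll) break; // could not improve
        bool small = smax * f < tol;
        ll = newll;
        if (small) { conv = true; break; }
      }
      if (conv) ++n_conv;
      double eta0 = beta[0];
      double vb0[3] = {1.0, t0, t0 * t0};
      for (int q = 1; q < p; ++q) eta0 += beta[q] * vb0[q];
      pv = logistic(eta0);
      if (pv < eps) pv = eps;
      if (pv > 1.0 - eps) pv = 1.0 - eps;
    }
    prob[pidx[v]] = pv;
  }
  return List::create(_["prob"] = prob, _["n_band"] = (double)B,
                      _["n_converged"] = n_conv, _["n_shortcut"] = n_short,
                      _["mean_bandwidth"] = h_sum / (double)B);
}
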