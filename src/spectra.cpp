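#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// LDL^T factorization + solve for a symmetric positive-definite
// pentadiagonal system. d0: main diagonal (n), d1: first off-diagonal
// (n-1), d2: second off-diagonal (n-2).
static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& b,
                        std::vector<double>& x) {
  const int n = (int)d0.size();
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0), u(n);
  for (int i = 0; i < n; ++i) {
    double l2 = 0.0, l1 = 0.0;
    if (i >= 2) l2 = d2[i - 2] / D[i - 2];
    if (i >= 1) {
      double a1 = d1[i - 1];
      if (i >= 2) a1 -= l2 * D[i - 2] * L1[i - 1];
      l1 = a1 / D[i - 1];
    }
    double di = d0[i];
    if (i >= 1) di -= l1 * l1 * D[i - 1];
    if (i >= 2) di -= l2 * l2 * D[i - 2];
    if (di <= 0.0) stop("pentadiagonal system not positive definite");
    D[i] = di; L1[i] = l1; L2[i] = l2;
  }
  for (int i = 0; i < n; ++i) {
    double v = b[i];
    if (i >= 1) v -= L1[i] * u[i - 1];
    if (i >= 2) v -= L2[i] * u[i - 2];
    u[i] = v;
  }
  for (int i = 0; i < n; ++i) u[i] /= D[i];
  for (int i = n - 1; i >= 0; --i) {
    double v = u[i];
    if (i + 1 < n) v -= L1[i + 1] * x[i + 1];
    if (i + 2 < n) v -= L2[i + 2] * x[i + 2];
    x[i] = v;
  }
}

// Asymmetric least squares baseline (Eilers & Boelens): iteratively solve
// (W + lambda * D2'D2) z = W y with w_i = p where y_i > z_i else 1-p.
// [[Rcpp::export]]
List asls_baseline_cpp(NumericVector y, double lambda, double p, int iters) {
  const int n = y.size();
  if (n < 5) stop("spectrum too short for baseline estimation");
  // stencil of D2'D2 for the (n-2) x n second-difference operator
  std::vector<double> dd0(n, 6.0), dd1(n - 1, -4.0), dd2(n - 2, 1.0);
  dd0[0] = dd0[n - 1] = 1.0;
  dd0[1] = dd0[n - 2] = 5.0;
  dd1[0] = dd1[n - 2] = -2.0;

  std::vector<double> w(n, 1.0), z(n, 0.0), d0(n), b(n);
  std::vector<double> d1(n - 1), d2(n - 2);
  for (int i = 0; i < n - 1; ++i) d1[i] = lambda * dd1[i];
  for (int i = 0; i < n - 2; ++i) d2[i] = lambda * dd2[i];

  int used = 0;
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      d0[i] = w[i] + lambda * dd0[i];
      b[i] = w[i] * y[i];
    }
    penta_solve(d0, d1, d2, b, z);
    ++used;
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double wn = (y[i] > z[i]) ? p : 1.0 - p;
      if (wn != w[i]) { w[i] = wn; changed = true; }
    }
    if (!changed) break;
  }
  return List::create(_["baseline"] = NumericVector(z.begin(), z.end()),
                      _["iterations"] = used);
}

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double m = v[n / 2];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
    m = 0.5 * (m + v[n / 2 - 1]);
  }
  return m;
}

// Running-median despiking: a point is a spike iff its deviation from the
// window median exceeds dynamic_factor * (scaled window MAD); spikes are
// replaced by the window median.
// [[Rcpp::export]]
List despike_cpp(NumericVector y, int half, double dynamic_factor) {
  const int n = y.size();
  NumericVector out = clone(y);
  std::vector<int> spikes;
  std::vector<double> win, dev;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    win.assign(y.begin() + lo, y.begin() + hi + 1);
    double med = median_of(win);
    dev.resize(win.size());
    for (size_t j = 0; j < win.size(); ++j) dev[j] = std::fabs(win[j] - med);
    double mad = 1.4826 * median_of(dev);
    double thr = dynamic_factor * mad + 1e-12 * std::max(1.0, std::fabs(med));
    if (std::fabs(y[i] - med) > thr) {
      out[i] = med;
      spikes.push_back(i + 1); // 1-based for R
    }
  }
  return List::create(_["intensity"] = out,
                      _["spike_index"] = IntegerVector(spikes.begin(), spikes.end()));
}
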