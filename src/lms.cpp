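#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// LMS adaptive-noise-cancellation sweeps.
//
// d: desired signal, r: reference (already power-normalised by the caller),
// w0: initial weights (length = taps). Each sweep runs the sample-by-sample
// update w <- w + 2*mu*x(n)*z(n) with x(n) the zero-padded lagged reference
// window, weights carried over between sweeps. Sweeping stops early when the
// sweep-level mean of z^2 improves by no more than tol (relative).
//
// Returns y, z of the final sweep, final weights, the per-sweep mean-square
// trajectory, a convergence flag, and a divergence flag (non-finite weights).
// [[Rcpp::export(name = ".lms_sweeps")]]
List lms_sweeps(NumericVector d, NumericVector r, NumericVector w0,
                double mu, int taps, int passes, double tol) {
  int N = d.size();
  NumericVector w = clone(w0);
  NumericVector y(N), z(N);
  std::vector<double> traj;
  traj.reserve(passes);
  bool converged = false, diverged = false;
  double prev = NA_REAL;

  for (int p = 0; p < passes; ++p) {
    for (int n = 0; n < N; ++n) {
      int m = std::min(taps, n + 1);
      double yn = 0.0;
      for (int j = 0; j < m; ++j) yn += w[j] * r[n - j];
      y[n] = yn;
      double zn = d[n] - yn;
      z[n] = zn;
      double g = 2.0 * mu * zn;
      for (int j = 0; j < m; ++j) w[j] += g * r[n - j];
    }
    for (int j = 0; j < taps; ++j) {
      if (!std::isfinite(w[j])) { diverged = true; break; }
    }
    double ms = 0.0;
    for (int n = 0; n < N; ++n) ms += z[n] * z[n];
    ms /= N;
    traj.push_back(ms);
    if (diverged) break;
    if (!ISNA(prev) && (prev - ms) <= tol * prev) { converged = true; break; }
    prev = ms;
  }

  return List::create(_["y"] = y, _["z"] = z, _["w"] = w,
                      _["mse_trajectory"] = wrap(traj),
                      _["converged"] = converged,
                      _["diverged"] = diverged);
}
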