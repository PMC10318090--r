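#include <Rcpp.h>
using namespace Rcpp;

// One Euler-Maruyama path of the two-patch population SDE.
//
// Coefficient vectors are precomputed on the step grid (left endpoints):
// r1[k] already contains the lethality term -delta*c_o(t_k); d12t[k] is the
// toxicant-amplified migration rate. z1, z2 are standard normal increments.
// scheme 0: EM on (x1, x2) with truncation at `floorv` (positivity floor);
// scheme 1: EM on (log x1, log x2) with Ito-corrected drift, exactly positive.
//
// Returns an (n_steps + 1) x 2 matrix of states.
// [[Rcpp::export]]
NumericMatrix em_path_core(double x10, double x20,
                           NumericVector r1, NumericVector r2,
                           NumericVector d12t, double d21,
                           double a1, double a2,
                           NumericVector s1, NumericVector s2,
                           NumericVector z1, NumericVector z2,
                           double dt, double floorv, int scheme,
                           double guard) {
  const int n = r1.size();
  if (r2.size() != n || d12t.size() != n || s1.size() != n ||
      s2.size() != n || z1.size() != n || z2.size() != n)
    stop("coefficient and increment vectors must share one length");
  NumericMatrix out(n + 1, 2);
  double x1 = x10, x2 = x20;
  const double sqdt = std::sqrt(dt);
  out(0, 0) = x1;
  out(0, 1) = x2;
  for (int k = 0; k < n; ++k) {
    const double dW1 = sqdt * z1[k];
    const double dW2 = sqdt * z2[k];
    if (scheme == 0) {
      const double d1 = x1 * (r1[k] - a1 * x1) + d21 * x2 - d12t[k] * x1;
      const double d2 = x2 * (r2[k] - a2 * x2) + d12t[k] * x1 - d21 * x2;
      x1 += d1 * dt + s1[k] * x1 * dW1;
      x2 += d2 * dt + s2[k] * x2 * dW2;
      if (x1 < floorv) x1 = floorv;
      if (x2 < floorv) x2 = floorv;
    } else {
      // d log x_i = (drift_i / x_i - 0.5 sigma_i^2) dt + sigma_i dW_i
      const double l1 = (r1[k] - a1 * x1 - d12t[k] + d21 * x2 / x1
                         - 0.5 * s1[k] * s1[k]) * dt + s1[k] * dW1;
      const double l2 = (r2[k] - a2 * x2 - d21 + d12t[k] * x1 / x2
                         - 0.5 * s2[k] * s2[k]) * dt + s2[k] * dW2;
      x1 *= std::exp(l1);
      x2 *= std::exp(l2);
    }
    if (!std::isfinite(x1) || !std::isfinite(x2) || x1 + x2 > guard)
      stop("simulation diverged at step %d (t = %g)", k + 1, (k + 1) * dt);
    out(k + 1, 0) = x1;
    out(k + 1, 1) = x2;
  }
  return out;
}
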