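#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// EM for a two-component univariate Gaussian mixture. Responsibilities are
// computed in log space (stable for points many sigmas away from both means);
// the M step uses the closed-form weighted moment updates. The per-iteration
// observed-data log-likelihood is recorded so callers can assert monotonicity.
// Observations may carry multiplicity weights `w` (a finely binned series
// behaves like the raw data up to the bin width).
// [[Rcpp::export]]
List em_gauss2_cpp(NumericVector x, NumericVector w,
                   double mu0, double sigma0, double pi0,
                   double mu1, double sigma1,
                   int max_iter, double tol, double sigma_floor) {
  const R_xlen_t n = x.size();
  if (w.size() != n) stop("weights must match data length");
  double wtot = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) wtot += w[i];
  const double LOG_SQRT_2PI = 0.5 * std::log(2.0 * M_PI);
  double pi1 = 1.0 - pi0;
  std::vector<double> ll_trace;
  ll_trace.reserve(max_iter);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    const double lp0 = std::log(pi0), lp1 = std::log(pi1);
    const double ls0 = std::log(sigma0), ls1 = std::log(sigma1);
    double ll = 0.0;
    double r0_sum = 0.0, r0_x = 0.0, r0_xx = 0.0;
    double r1_sum = 0.0, r1_x = 0.0, r1_xx = 0.0;

    for (R_xlen_t i = 0; i < n; ++i) {
      const double d0 = (x[i] - mu0) / sigma0;
      const double d1 = (x[i] - mu1) / sigma1;
      const double la = lp0 - ls0 - 0.5 * d0 * d0;
      const double lb = lp1 - ls1 - 0.5 * d1 * d1;
      const double m = la > lb ? la : lb;
      const double ea = std::exp(la - m), eb = std::exp(lb - m);
      const double denom = ea + eb;
      ll += w[i] * (m + std::log(denom) - LOG_SQRT_2PI);
      const double r0 = w[i] * ea / denom;
      const double r1 = w[i] - r0;
      r0_sum += r0; r0_x += r0 * x[i]; r0_xx += r0 * x[i] * x[i];
      r1_sum += r1; r1_x += r1 * x[i]; r1_xx += r1 * x[i] * x[i];
    }
    ll_trace.push_back(ll);

    if (iter > 0 && std::abs(ll - ll_trace[iter - 1]) < tol) {
      converged = true;
      break;
    }

    if (r0_sum > 0) {
      mu0 = r0_x / r0_sum;
      double v0 = r0_xx / r0_sum - mu0 * mu0;
      sigma0 = std::sqrt(v0 > 0 ? v0 : 0.0);
    }
    if (r1_sum > 0) {
      mu1 = r1_x / r1_sum;
      double v1 = r1_xx / r1_sum - mu1 * mu1;
      sigma1 = std::sqrt(v1 > 0 ? v1 : 0.0);
    }
    if (sigma0 < sigma_floor) sigma0 = sigma_floor;
    if (sigma1 < sigma_floor) sigma1 = sigma_floor;
    pi0 = r0_sum / wtot;
    pi1 = 1.0 - pi0;
    if (pi0 <= 0) { pi0 = 1e-12; pi1 = 1.0 - pi0; }
    if (pi1 <= 0) { pi1 = 1e-12; pi0 = 1.0 - pi1; }
  }

  return List::create(
    _["mu"] = NumericVector::create(mu0, mu1),
    _["sigma"] = NumericVector::create(sigma0, sigma1),
    _["pi"] = NumericVector::create(pi0, pi1),
    _["loglik_trace"] = wrap(ll_trace),
    _["n_iter"] = static_cast<int>(ll_trace.size()),
    _["converged"] = converged);
}
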