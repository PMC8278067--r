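#include <Rcpp.h>
#include "wiener.h"
using namespace Rcpp;

// Density of the first-passage time through the LOWER boundary for a
// driftless unit-diffusion on (0, 1) started at w, evaluated at normalized
// time u = t / a^2.  Adaptive truncation between the small-time and
// large-time series with absolute tolerance eps (Navarro-Fuss style bounds).
double wiener_fpt_std(double u, double w, double eps) {
  if (!R_FINITE(u) || u <= 0.0) return 0.0;

  double ks = 2.0;
  double arg_s = 2.0 * eps * std::sqrt(2.0 * M_PI * u);
  if (arg_s < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(arg_s));
    double lb = std::sqrt(u) + 1.0;
    if (ks < lb) ks = lb;
  }

  double kl = 1.0 / (M_PI * std::sqrt(u));
  double arg_l = M_PI * u * eps;
  if (arg_l < 1.0) {
    double t = std::sqrt(-2.0 * std::log(arg_l) / (M_PI * M_PI * u));
    if (t > kl) kl = t;
  }

  double f = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Log density of the first passage through the lower boundary at decision
// time t (after non-decision time has been subtracted), drift v, boundary
// separation a, relative start point w.
double wiener_lpdf_lower(double t, double v, double a, double w, double eps) {
  if (!R_FINITE(t) || t <= 0.0 || !R_FINITE(v) || a <= 0.0 ||
      w <= 0.0 || w >= 1.0)
    return R_NegInf;
  double u = t / (a * a);
  double f = wiener_fpt_std(u, w, eps);
  if (f <= 0.0) return R_NegInf;
  return std::log(f) - 2.0 * std::log(a) - v * a * w - v * v * t / 2.0;
}

// Reflection identity: upper-boundary density at (v, w) equals the
// lower-boundary density at (-v, 1 - w).
double wiener_lpdf(double t, double v, double a, double w, bool upper,
                   double eps) {
  return upper ? wiener_lpdf_lower(t, -v, a, 1.0 - w, eps)
               : wiener_lpdf_lower(t, v, a, w, eps);
}

// [[Rcpp::export]]
NumericVector dwiener_cpp(NumericVector t, double v, double a, double w,
                          bool upper, bool log_d, double eps) {
  R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double l = wiener_lpdf(t[i], v, a, w, upper, eps);
    out[i] = log_d ? l : std::exp(l);
  }
  return out;
}

// Euler-Maruyama forward simulation.  boundary: 1 = upper, 0 = lower,
// NA = no crossing before `horizon` seconds of decision time.
// [[Rcpp::export]]
List rwiener_cpp(int n, double v, double a, double w, double t0,
                 double dt, double horizon) {
  NumericVector rt(n);
  IntegerVector boundary(n);
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    double t = 0.0;
    int b = NA_INTEGER;
    while (t < horizon) {
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { b = 1; break; }
      if (x <= 0.0) { b = 0; break; }
    }
    boundary[i] = b;
    rt[i] = (b == NA_INTEGER) ? NA_REAL : t + t0;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}
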