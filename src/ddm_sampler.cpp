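#include <Rcpp.h>
#include "slice.h"
#include "wiener.h"
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Parameter slots per subject (P = 11), cell-means coding of the 2x2
// (target expression x required response) design:
//   0..3   drift v by cell                (identity)
//   4..7   boundary separation by cell    (exp)
//   8..9   start bias z by target expr    (logistic)
//   10     non-decision time t0           (logistic * 0.95 * min subject rt)
// Cells are ordered ss, sf, fs, ff (target, required); expr 0 = smile.

static const int DP = 11;

// [[Rcpp::export]]
List ddm_sampler_cpp(IntegerVector subj, IntegerVector cell, IntegerVector expr,
                     IntegerVector upper, NumericVector rt, int S,
                     int n_iter, int n_warmup,
                     NumericVector prior_mu_sd, NumericVector prior_sigma_sd,
                     NumericVector mu_init, NumericVector sigma_init,
                     double eps, double slice_w, int slice_m) {
  int N = subj.size();
  std::vector<int> st(S + 1, 0);
  for (int i = 0; i < N; ++i) st[subj[i] + 1]++;
  for (int s = 0; s < S; ++s) st[s + 1] += st[s];
  const int *pc = INTEGER(cell), *pe = INTEGER(expr), *pu = INTEGER(upper);
  const double *prt = REAL(rt);

  std::vector<double> t0max(S);
  for (int s = 0; s < S; ++s) {
    double m = R_PosInf;
    for (int i = st[s]; i < st[s + 1]; ++i)
      if (prt[i] < m) m = prt[i];
    t0max[s] = 0.95 * m;
  }

  std::vector<double> mu(DP), ls(DP), raw(S * DP, 0.0);
  for (int p = 0; p < DP; ++p) {
    mu[p] = mu_init[p];
    ls[p] = std::log(sigma_init[p]);
  }

  auto natural = [&](int s, double *th) {
    for (int p = 0; p < DP; ++p) {
      double x = mu[p] + std::exp(ls[p]) * raw[s * DP + p];
      if (p < 4) th[p] = x;                       // v
      else if (p < 8) th[p] = std::exp(x);        // a
      else if (p < 10) th[p] = inv_logit(x);      // z
      else th[p] = inv_logit(x) * t0max[s];       // t0
    }
  };
  auto sub_ll = [&](int s) -> double {
    double th[DP];
    natural(s, th);
    double ll = 0.0;
    for (int i = st[s]; i < st[s + 1]; ++i) {
      int c = pc[i];
      double d = prt[i] - th[10];
      ll += wiener_lpdf(d, th[c], th[4 + c], th[8 + pe[i]], pu[i] == 1, eps);
    }
    return ll;
  };

  std::vector<double> subll(S);
  for (int s = 0; s < S; ++s) subll[s] = sub_ll(s);

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, 2 * DP + S * DP);

  RNGScope scope;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int p = 0; p < DP; ++p) {
      auto g = [&](double x) -> double {
        double old = mu[p];
        mu[p] = x;
        double lp = R::dnorm(x, 0.0, prior_mu_sd[p], 1);
        for (int s = 0; s < S; ++s) lp += sub_ll(s);
        mu[p] = old;
        return lp;
      };
      double g0 = R::dnorm(mu[p], 0.0, prior_mu_sd[p], 1);
      for (int s = 0; s < S; ++s) g0 += subll[s];
      mu[p] = slice_sample(mu[p], g0, g, slice_w, slice_m);
      for (int s = 0; s < S; ++s) subll[s] = sub_ll(s);
    }
    for (int p = 0; p < DP; ++p) {
      auto g = [&](double x) -> double {
        double old = ls[p];
        ls[p] = x;
        double lp = R::dnorm(std::exp(x), 0.0, prior_sigma_sd[p], 1) + x;
        for (int s = 0; s < S; ++s) lp += sub_ll(s);
        ls[p] = old;
        return lp;
      };
      double g0 = R::dnorm(std::exp(ls[p]), 0.0, prior_sigma_sd[p], 1) + ls[p];
      for (int s = 0; s < S; ++s) g0 += subll[s];
      ls[p] = slice_sample(ls[p], g0, g, slice_w, slice_m);
      for (int s = 0; s < S; ++s) subll[s] = sub_ll(s);
    }
    for (int s = 0; s < S; ++s) {
      for (int p = 0; p < DP; ++p) {
        int idx = s * DP + p;
        auto g = [&](double x) -> double {
          double old = raw[idx];
          raw[idx] = x;
          double lp = R::dnorm(x, 0.0, 1.0, 1) + sub_ll(s);
          raw[idx] = old;
          return lp;
        };
        double g0 = R::dnorm(raw[idx], 0.0, 1.0, 1) + subll[s];
        raw[idx] = slice_sample(raw[idx], g0, g, slice_w, slice_m);
        subll[s] = sub_ll(s);
      }
    }
    if (iter >= n_warmup) {
      int k = iter - n_warmup;
      for (int p = 0; p < DP; ++p) {
        draws(k, p) = mu[p];
        draws(k, DP + p) = std::exp(ls[p]);
      }
      double th[DP];
      for (int s = 0; s < S; ++s) {
        natural(s, th);
        for (int p = 0; p < DP; ++p) draws(k, 2 * DP + s * DP + p) = th[p];
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["t0_max"] = NumericVector(t0max.begin(), t0max.end()));
}
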