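#include <Rcpp.h>
#include "slice.h"
using namespace Rcpp;

// Model codes (must match rl_model_spec() on the R side):
//   0 baseline_no_bias  params: alpha, beta
//   1 copy_bias         params: alpha, beta, zeta
//   2 prior_bias_only   params: alpha, beta, q0   (zeta fixed at 0;
//                       q0 is a learnable initial value of Q_copy)
//   3 expr_dep_alpha    params: alpha_smile, alpha_frown, beta, zeta
//   4 expr_dep_zeta     params: alpha, beta, zeta_smile, zeta_frown

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double log_plogis(double x) {
  return x > 0.0 ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

static int rl_npar(int model) {
  switch (model) {
    case 0: return 2;
    case 1: case 2: return 3;
    default: return 4;
  }
}

// slot constraint types: 1 -> logistic to [0,1], 2 -> 2*logistic to (0,2),
// 0 -> identity (unconstrained)
static void rl_slot_types(int model, int *ty) {
  switch (model) {
    case 0: ty[0] = 1; ty[1] = 2; break;
    case 1: ty[0] = 1; ty[1] = 2; ty[2] = 0; break;
    case 2: ty[0] = 1; ty[1] = 2; ty[2] = 0; break;
    case 3: ty[0] = 1; ty[1] = 1; ty[2] = 2; ty[3] = 0; break;
    default: ty[0] = 1; ty[1] = 2; ty[2] = 0; ty[3] = 0; break;
  }
}

static inline double transform_slot(double x, int ty) {
  if (ty == 1) return inv_logit(x);
  if (ty == 2) return 2.0 * inv_logit(x);
  return x;
}

// Log likelihood of one subject's ordered trial sequence under natural-scale
// parameters th.  expr: 0 = smile, 1 = frown; inter: 0/1; choice: 1 = copy.
// If pw is non-null it receives per-trial log probabilities.
static double rl_subject_ll(int model, const double *th,
                            const int *inter, const int *expr,
                            const int *choice, const double *r,
                            int n, double *pw) {
  double Q[2][2] = {{0.0, 0.0}, {0.0, 0.0}};  // [interactant][0 = not, 1 = copy]
  if (model == 2) { Q[0][1] = th[2]; Q[1][1] = th[2]; }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double alpha, beta, zeta;
    switch (model) {
      case 0: alpha = th[0]; beta = th[1]; zeta = 0.0; break;
      case 1: alpha = th[0]; beta = th[1]; zeta = th[2]; break;
      case 2: alpha = th[0]; beta = th[1]; zeta = 0.0; break;
      case 3: alpha = th[expr[i]]; beta = th[2]; zeta = th[3]; break;
      default: alpha = th[0]; beta = th[1];
               zeta = (expr[i] == 0) ? th[2] : th[3]; break;
    }
    int it = inter[i];
    double d = (Q[it][1] + zeta - Q[it][0]) / beta;
    double lpi = choice[i] ? log_plogis(d) : log_plogis(-d);
    ll += lpi;
    if (pw) pw[i] = lpi;
    int c = choice[i];
    Q[it][c] += alpha * (r[i] - Q[it][c]);
  }
  return ll;
}

static void subject_offsets(const int *subj, int N, int S, std::vector<int> &st) {
  st.assign(S + 1, 0);
  for (int i = 0; i < N; ++i) st[subj[i] + 1]++;
  for (int s = 0; s < S; ++s) st[s + 1] += st[s];
}

// theta: S x P natural-scale parameter matrix, one row per subject.
// [[Rcpp::export]]
List rl_loglik_cpp(IntegerVector subj, IntegerVector inter, IntegerVector expr,
                   IntegerVector choice, NumericVector r,
                   NumericMatrix theta, int model, bool pointwise) {
  int N = subj.size(), S = theta.nrow(), P = rl_npar(model);
  if (theta.ncol() != P) stop("theta has wrong number of columns");
  std::vector<int> st;
  subject_offsets(INTEGER(subj), N, S, st);
  const int *pi = INTEGER(inter), *pe = INTEGER(expr), *pc = INTEGER(choice);
  const double *pr = REAL(r);
  NumericVector pw;
  double *ppw = nullptr;
  if (pointwise) { pw = NumericVector(N); ppw = REAL(pw); }
  double total = 0.0;
  std::vector<double> th(P);
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < P; ++p) th[p] = theta(s, p);
    total += rl_subject_ll(model, th.data(), pi + st[s], pe + st[s],
                           pc + st[s], pr + st[s], st[s + 1] - st[s],
                           ppw ? ppw + st[s] : nullptr);
  }
  return List::create(_["total"] = total,
                      _["pointwise"] = pointwise ? (SEXP)pw : R_NilValue);
}

// Hierarchical sampler: componentwise slice sampling on the unconstrained
// scale.  Subject parameter = transform(mu_p + sigma_p * raw_sp) with
// standard-normal priors on raw, N(0, prior_mu_sd) on mu and half-normal
// (prior_sigma_sd) on sigma (non-centered parameterization).
// [[Rcpp::export]]
List rl_sampler_cpp(IntegerVector subj, IntegerVector inter, IntegerVector expr,
                    IntegerVector choice, NumericVector r, int S, int model,
                    int n_iter, int n_warmup, bool keep_loglik,
                    NumericVector prior_mu_sd, NumericVector prior_sigma_sd,
                    double slice_w, int slice_m) {
  int N = subj.size(), P = rl_npar(model);
  std::vector<int> ty(P);
  rl_slot_types(model, ty.data());
  std::vector<int> st;
  subject_offsets(INTEGER(subj), N, S, st);
  const int *pi = INTEGER(inter), *pe = INTEGER(expr), *pc = INTEGER(choice);
  const double *pr = REAL(r);

  std::vector<double> mu(P, 0.0), ls(P, std::log(0.5)), raw(S * P, 0.0);

  auto natural = [&](int s, double *th) {
    for (int p = 0; p < P; ++p)
      th[p] = transform_slot(mu[p] + std::exp(ls[p]) * raw[s * P + p], ty[p]);
  };
  auto sub_ll = [&](int s) -> double {
    double th[4];
    natural(s, th);
    return rl_subject_ll(model, th, pi + st[s], pe + st[s], pc + st[s],
                         pr + st[s], st[s + 1] - st[s], nullptr);
  };

  std::vector<double> subll(S);
  for (int s = 0; s < S; ++s) subll[s] = sub_ll(s);

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, 2 * P + S * P);
  NumericMatrix pw_ll = keep_loglik ? NumericMatrix(n_keep, N)
                                    : NumericMatrix(0, 0);

  RNGScope scope;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int p = 0; p < P; ++p) {  // population locations
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
    for (int p = 0; p < P; ++p) {  // population log scales
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
    for (int s = 0; s < S; ++s) {  // subject offsets
      for (int p = 0; p < P; ++p) {
        int idx = s * P + p;
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
      for (int p = 0; p < P; ++p) {
        draws(k, p) = mu[p];
        draws(k, P + p) = std::exp(ls[p]);
      }
      double th[4];
      for (int s = 0; s < S; ++s) {
        natural(s, th);
        for (int p = 0; p < P; ++p) draws(k, 2 * P + s * P + p) = th[p];
        if (keep_loglik) {
          std::vector<double> pw(st[s + 1] - st[s]);
          rl_subject_ll(model, th, pi + st[s], pe + st[s], pc + st[s],
                        pr + st[s], st[s + 1] - st[s], pw.data());
          for (int i = 0; i < (int)pw.size(); ++i)
            pw_ll(k, st[s] + i) = pw[i];
        }
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["loglik"] = keep_loglik ? (SEXP)pw_ll : R_NilValue);
}

// Posterior-predictive simulation for ONE subject.  theta: draws x P
// natural-scale parameters.  copy_correct[i] = 1 if the copy action avoids
// the shock on trial i.  cellid maps each trial to an output cell
// (condition x relative trial number); returns draws x ncell mean correct
// rates, each averaged over nsims simulated runs of the schedule.
// [[Rcpp::export]]
NumericMatrix rl_predict_cpp(NumericMatrix theta, int model,
                             IntegerVector inter, IntegerVector expr,
                             IntegerVector copy_correct, IntegerVector cellid,
                             int ncell, int nsims) {
  int n = inter.size(), D = theta.nrow(), P = theta.ncol();
  if (P != rl_npar(model)) stop("theta has wrong number of columns");
  std::vector<int> cellcount(ncell, 0);
  for (int i = 0; i < n; ++i) cellcount[cellid[i]]++;
  NumericMatrix out(D, ncell);
  RNGScope scope;
  std::vector<double> th(P), acc(ncell);
  for (int d = 0; d < D; ++d) {
    for (int p = 0; p < P; ++p) th[p] = theta(d, p);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < nsims; ++s) {
      double Q[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
      if (model == 2) { Q[0][1] = th[2]; Q[1][1] = th[2]; }
      for (int i = 0; i < n; ++i) {
        double alpha, beta, zeta;
        switch (model) {
          case 0: alpha = th[0]; beta = th[1]; zeta = 0.0; break;
          case 1: alpha = th[0]; beta = th[1]; zeta = th[2]; break;
          case 2: alpha = th[0]; beta = th[1]; zeta = 0.0; break;
          case 3: alpha = th[expr[i]]; beta = th[2]; zeta = th[3]; break;
          default: alpha = th[0]; beta = th[1];
                   zeta = (expr[i] == 0) ? th[2] : th[3]; break;
        }
        int it = inter[i];
        double p_copy = inv_logit((Q[it][1] + zeta - Q[it][0]) / beta);
        int c = (unif_rand() < p_copy) ? 1 : 0;
        int corr = (c == copy_correct[i]) ? 1 : 0;
        acc[cellid[i]] += corr;
        double rr = corr ? 1.0 : -1.0;
        Q[it][c] += alpha * (rr - Q[it][c]);
      }
    }
    for (int c2 = 0; c2 < ncell; ++c2)
      out(d, c2) = cellcount[c2] > 0
                       ? acc[c2] / ((double)nsims * cellcount[c2])
                       : NA_REAL;
  }
  return out;
}
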