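#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state Gaussian hidden Markov model fitted by Baum-Welch
// (expectation-maximization) with scaled forward-backward recursions.
// Initial parameters are supplied by the caller (deterministic median-split
// initialization), so the fit itself is fully deterministic.

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// [[Rcpp::export(name = ".hmm2_em")]]
List hmm2_em(NumericVector x, NumericVector mu0, NumericVector sd0,
             NumericVector pi0, NumericMatrix A0, int max_iter,
             double tol) {
  int T = x.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), pi = clone(pi0);
  NumericMatrix A = clone(A0);
  NumericMatrix alpha(T, 2), beta(T, 2), gamma(T, 2);
  NumericVector c(T);
  NumericVector ll_trace;
  double ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission probabilities (work in probability space with scaling)
    // forward
    double e0 = std::exp(dnorm_log(x[0], mu[0], sd[0]));
    double e1 = std::exp(dnorm_log(x[0], mu[1], sd[1]));
    alpha(0, 0) = pi[0] * e0;
    alpha(0, 1) = pi[1] * e1;
    c[0] = alpha(0, 0) + alpha(0, 1);
    if (c[0] <= 0) c[0] = DBL_MIN;
    alpha(0, 0) /= c[0];
    alpha(0, 1) /= c[0];
    for (int t = 1; t < T; ++t) {
      e0 = std::exp(dnorm_log(x[t], mu[0], sd[0]));
      e1 = std::exp(dnorm_log(x[t], mu[1], sd[1]));
      double a0 = (alpha(t - 1, 0) * A(0, 0) + alpha(t - 1, 1) * A(1, 0)) * e0;
      double a1 = (alpha(t - 1, 0) * A(0, 1) + alpha(t - 1, 1) * A(1, 1)) * e1;
      c[t] = a0 + a1;
      if (c[t] <= 0) c[t] = DBL_MIN;
      alpha(t, 0) = a0 / c[t];
      alpha(t, 1) = a1 / c[t];
    }
    // backward
    beta(T - 1, 0) = 1.0;
    beta(T - 1, 1) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double f0 = std::exp(dnorm_log(x[t + 1], mu[0], sd[0]));
      double f1 = std::exp(dnorm_log(x[t + 1], mu[1], sd[1]));
      beta(t, 0) = (A(0, 0) * f0 * beta(t + 1, 0) +
                    A(0, 1) * f1 * beta(t + 1, 1)) / c[t + 1];
      beta(t, 1) = (A(1, 0) * f0 * beta(t + 1, 0) +
                    A(1, 1) * f1 * beta(t + 1, 1)) / c[t + 1];
    }
    // posteriors and expected transition counts
    double n00 = 0, n01 = 0, n10 = 0, n11 = 0;
    for (int t = 0; t < T; ++t) {
      double g0 = alpha(t, 0) * beta(t, 0);
      double g1 = alpha(t, 1) * beta(t, 1);
      double s = g0 + g1;
      if (s <= 0) s = DBL_MIN;
      gamma(t, 0) = g0 / s;
      gamma(t, 1) = g1 / s;
    }
    for (int t = 0; t < T - 1; ++t) {
      double f0 = std::exp(dnorm_log(x[t + 1], mu[0], sd[0]));
      double f1 = std::exp(dnorm_log(x[t + 1], mu[1], sd[1]));
      double x00 = alpha(t, 0) * A(0, 0) * f0 * beta(t + 1, 0) / c[t + 1];
      double x01 = alpha(t, 0) * A(0, 1) * f1 * beta(t + 1, 1) / c[t + 1];
      double x10 = alpha(t, 1) * A(1, 0) * f0 * beta(t + 1, 0) / c[t + 1];
      double x11 = alpha(t, 1) * A(1, 1) * f1 * beta(t + 1, 1) / c[t + 1];
      double s = x00 + x01 + x10 + x11;
      if (s <= 0) s = DBL_MIN;
      n00 += x00 / s;
      n01 += x01 / s;
      n10 += x10 / s;
      n11 += x11 / s;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(c[t]);
    ll_trace.push_back(ll);
    if (iter > 0 && std::fabs(ll - ll_old) < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M step
    for (int k = 0; k < 2; ++k) {
      double w = 0, wx = 0;
      for (int t = 0; t < T; ++t) {
        w += gamma(t, k);
        wx += gamma(t, k) * x[t];
      }
      if (w <= 0) w = DBL_MIN;
      mu[k] = wx / w;
      double wv = 0;
      for (int t = 0; t < T; ++t) {
        double d = x[t] - mu[k];
        wv += gamma(t, k) * d * d;
      }
      sd[k] = std::sqrt(wv / w);
      if (sd[k] < 1e-3) sd[k] = 1e-3;
      pi[k] = gamma(0, k);
    }
    double r0 = n00 + n01, r1 = n10 + n11;
    if (r0 <= 0) r0 = DBL_MIN;
    if (r1 <= 0) r1 = DBL_MIN;
    A(0, 0) = n00 / r0;
    A(0, 1) = n01 / r0;
    A(1, 0) = n10 / r1;
    A(1, 1) = n11 / r1;
    // keep transitions away from exact 0/1
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        if (A(i, j) < 1e-8) A(i, j) = 1e-8;
        if (A(i, j) > 1 - 1e-8) A(i, j) = 1 - 1e-8;
      }
  }

  NumericVector post1(T);
  for (int t = 0; t < T; ++t) post1[t] = gamma(t, 1);
  return List::create(
    _["mu"] = mu, _["sd"] = sd, _["pi"] = pi, _["A"] = A,
    _["posterior_state2"] = post1,
    _["loglik_trace"] = ll_trace,
    _["converged"] = converged,
    _["iterations"] = iter + 1
  );
}
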