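#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d > 1e-300 ? d : 1e-300;
}

// Scaled forward-backward (E-step) for a two-state Gaussian HMM over one or
// more independent chains sharing parameters.  block_start holds 1-based
// start indices of the chains; the initial distribution is re-applied at
// every chain start.  Returns the total log-likelihood and the sufficient
// statistics needed for the Baum-Welch M-step.
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericVector x, NumericVector mu, NumericVector sigma,
               NumericMatrix trans, NumericVector init,
               IntegerVector block_start) {
  const int n = x.size();
  const int nb = block_start.size();
  NumericMatrix gamma(n, 2);
  NumericMatrix xi_sum(2, 2);
  NumericVector gamma_first(2);
  double loglik = 0.0;

  std::vector<double> a0(n), a1(n), c(n);

  for (int b = 0; b < nb; ++b) {
    int s = block_start[b] - 1;
    int e = (b + 1 < nb) ? block_start[b + 1] - 1 : n;  // exclusive
    // forward
    double b0 = gauss(x[s], mu[0], sigma[0]);
    double b1 = gauss(x[s], mu[1], sigma[1]);
    double f0 = init[0] * b0, f1 = init[1] * b1;
    double ct = f0 + f1;
    if (!(ct > 0) || !std::isfinite(ct))
      stop("non-finite likelihood in forward recursion");
    a0[s] = f0 / ct; a1[s] = f1 / ct; c[s] = ct;
    loglik += std::log(ct);
    for (int t = s + 1; t < e; ++t) {
      b0 = gauss(x[t], mu[0], sigma[0]);
      b1 = gauss(x[t], mu[1], sigma[1]);
      f0 = (a0[t - 1] * trans(0, 0) + a1[t - 1] * trans(1, 0)) * b0;
      f1 = (a0[t - 1] * trans(0, 1) + a1[t - 1] * trans(1, 1)) * b1;
      ct = f0 + f1;
      if (!(ct > 0) || !std::isfinite(ct))
        stop("non-finite likelihood in forward recursion");
      a0[t] = f0 / ct; a1[t] = f1 / ct; c[t] = ct;
      loglik += std::log(ct);
    }
    // backward + accumulate
    double be0 = 1.0, be1 = 1.0;
    gamma(e - 1, 0) = a0[e - 1]; gamma(e - 1, 1) = a1[e - 1];
    for (int t = e - 2; t >= s; --t) {
      double eb0 = gauss(x[t + 1], mu[0], sigma[0]);
      double eb1 = gauss(x[t + 1], mu[1], sigma[1]);
      double nb0 = (trans(0, 0) * eb0 * be0 + trans(0, 1) * eb1 * be1)
                   / c[t + 1];
      double nb1 = (trans(1, 0) * eb0 * be0 + trans(1, 1) * eb1 * be1)
                   / c[t + 1];
      xi_sum(0, 0) += a0[t] * trans(0, 0) * eb0 * be0 / c[t + 1];
      xi_sum(0, 1) += a0[t] * trans(0, 1) * eb1 * be1 / c[t + 1];
      xi_sum(1, 0) += a1[t] * trans(1, 0) * eb0 * be0 / c[t + 1];
      xi_sum(1, 1) += a1[t] * trans(1, 1) * eb1 * be1 / c[t + 1];
      be0 = nb0; be1 = nb1;
      gamma(t, 0) = a0[t] * be0;
      gamma(t, 1) = a1[t] * be1;
    }
    gamma_first[0] += gamma(s, 0);
    gamma_first[1] += gamma(s, 1);
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum, _["gamma_first"] = gamma_first);
}

// Viterbi decoding (log space), chains restarted at each block start.
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu,
                          NumericVector sigma, NumericMatrix trans,
                          NumericVector init, IntegerVector block_start) {
  const int n = x.size();
  const int nb = block_start.size();
  IntegerVector path(n);
  double lt00 = std::log(trans(0, 0)), lt01 = std::log(trans(0, 1));
  double lt10 = std::log(trans(1, 0)), lt11 = std::log(trans(1, 1));
  std::vector<double> v0(n), v1(n);
  std::vector<int> p0(n), p1(n);

  for (int b = 0; b < nb; ++b) {
    int s = block_start[b] - 1;
    int e = (b + 1 < nb) ? block_start[b + 1] - 1 : n;
    v0[s] = std::log(init[0]) + std::log(gauss(x[s], mu[0], sigma[0]));
    v1[s] = std::log(init[1]) + std::log(gauss(x[s], mu[1], sigma[1]));
    for (int t = s + 1; t < e; ++t) {
      double e0 = std::log(gauss(x[t], mu[0], sigma[0]));
      double e1 = std::log(gauss(x[t], mu[1], sigma[1]));
      double from0 = v0[t - 1] + lt00, from1 = v1[t - 1] + lt10;
      if (from0 >= from1) { v0[t] = from0 + e0; p0[t] = 0; }
      else                { v0[t] = from1 + e0; p0[t] = 1; }
      from0 = v0[t - 1] + lt01; from1 = v1[t - 1] + lt11;
      if (from0 >= from1) { v1[t] = from0 + e1; p1[t] = 0; }
      else                { v1[t] = from1 + e1; p1[t] = 1; }
    }
    int st = (v0[e - 1] >= v1[e - 1]) ? 0 : 1;
    path[e - 1] = st + 1;
    for (int t = e - 1; t > s; --t) {
      st = (st == 0) ? p0[t] : p1[t];
      path[t - 1] = st + 1;
    }
  }
  return path;
}
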