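#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for an HMM with diagonal-Gaussian emissions.
// obs:   T x D observation matrix
// means: K x D state means
// vars:  K x D state variances (all > 0)
// trans: K x K row-stochastic transition matrix
// init:  length-K initial state distribution
// Returns per-base posterior marginals (T x K, rows sum to 1) and the
// log-likelihood. Per-position scaling makes underflow impossible.
// [[Rcpp::export]]
List forward_backward_gaussian(NumericMatrix obs, NumericMatrix means,
                               NumericMatrix vars, NumericMatrix trans,
                               NumericVector init) {
  const int T = obs.nrow(), D = obs.ncol(), K = means.nrow();
  if (means.ncol() != D || vars.nrow() != K || vars.ncol() != D ||
      trans.nrow() != K || trans.ncol() != K || init.size() != K)
    stop("dimension mismatch");

  // emission log-densities
  NumericMatrix logB(T, K);
  std::vector<double> cst(K, 0.0);
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    for (int d = 0; d < D; ++d) {
      if (vars(k, d) <= 0) stop("non-positive variance");
      cst[k] += -0.5 * (l2pi + std::log(vars(k, d)));
    }
  }
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double s = cst[k];
      for (int d = 0; d < D; ++d) {
        double z = obs(t, d) - means(k, d);
        s += -0.5 * z * z / vars(k, d);
      }
      logB(t, k) = s;
    }

  // per-position max-shifted emissions
  NumericMatrix b(T, K);
  std::vector<double> shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
    shift[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  std::vector<double> c(T);
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s0 += alpha(0, k); }
  if (s0 <= 0) stop("zero forward mass at position 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  c[0] = s0;
  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= b(t, k);
      alpha(t, k) = a;
      st += a;
    }
    if (st <= 0) stop("zero forward mass");
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
    c[t] = st;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j)
        v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = v / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + shift[t];
  return List::create(_["posterior"] = gamma, _["loglik"] = ll);
}
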