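#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion. `dens` is the T x K emission density matrix on
// the natural scale (callers shift by the per-row max of the log densities
// to avoid underflow and add the shifts back to the log-likelihood).
// Returns sum(log c_t), the log-likelihood up to that shift.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix dens, NumericMatrix A, NumericVector pi) {
  const int T = dens.nrow(), K = dens.ncol();
  std::vector<double> alpha(K), alpha_new(K);
  double ll = 0.0, s = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * dens(0, k); s += alpha[k]; }
  if (s <= 0.0) stop("observation has zero likelihood under the model");
  ll += std::log(s);
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha[i] * A(i, j);
      a *= dens(t, j);
      alpha_new[j] = a;
      s += a;
    }
    if (s <= 0.0) stop("observation has zero likelihood under the model");
    ll += std::log(s);
    for (int j = 0; j < K; ++j) alpha[j] = alpha_new[j] / s;
  }
  return ll;
}

// Scaled forward-backward pass for one observation sequence. Returns the
// posterior state matrix gamma (T x K), the summed transition posteriors
// xi_sum (K x K), and the scaled log-likelihood.
// [[Rcpp::export]]
List hmm_fb_cpp(NumericMatrix dens, NumericMatrix A, NumericVector pi) {
  const int T = dens.nrow(), K = dens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);
  double ll = 0.0, s = 0.0;

  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * dens(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("observation has zero likelihood under the model");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= dens(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("observation has zero likelihood under the model");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * dens(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * beta(t, k);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * dens(t + 1, j) * beta(t + 1, j) / c[t + 1];

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["loglik"] = ll);
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict improvement required to switch). Returns a 0-based path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix logA,
                              NumericVector logpi) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logdens(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
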