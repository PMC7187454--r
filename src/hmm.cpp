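#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one chain.
// B is the T x K matrix of per-bin emission likelihoods (any positive
// per-row scaling is allowed; it cancels in gamma/xi and shifts the
// log-likelihood by the sum of the log row scalings, handled in R).
// Returns total log-likelihood (sum of log scaling factors), posterior
// marginals gamma (T x K) and expected transition counts xi (K x K,
// summed over t).
// [[Rcpp::export]]
List fb_cpp(NumericVector init, NumericMatrix trans, NumericMatrix B) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * B(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("zero forward mass at position 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero forward mass at position %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward (same scaling constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += trans(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  // posteriors and expected transition counts
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      double aj = alpha(t, j);
      for (int k = 0; k < K; ++k) {
        xi(j, k) += aj * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in log space. logB is T x K. Ties broken toward the
// smallest state index (strict improvement required to switch).
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericVector log_init, NumericMatrix log_trans,
                          NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_init[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + log_trans(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + log_trans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) {
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// First-order Markov chain by inverse-CDF sampling from pre-drawn
// uniforms (RNG stays in R, so streams are reproducible). 1-based states.
// [[Rcpp::export]]
IntegerVector sim_markov_cpp(NumericVector init, NumericMatrix trans,
                             NumericVector u) {
  const int T = u.size(), K = init.size();
  IntegerVector out(T);
  double acc = 0.0;
  int s = K - 1;
  for (int k = 0; k < K; ++k) {
    acc += init[k];
    if (u[0] <= acc) { s = k; break; }
  }
  out[0] = s + 1;
  for (int t = 1; t < T; ++t) {
    acc = 0.0;
    int nxt = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += trans(s, k);
      if (u[t] <= acc) { nxt = k; break; }
    }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}
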