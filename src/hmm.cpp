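#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a Gaussian HMM given per-frame per-state
// log-densities. Returns log-likelihood, posteriors (gamma), and summed
// transition counts (xi).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericMatrix transmat,
                          NumericVector initprob) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector scale(T);

  // shift log densities per frame for numerical stability
  NumericMatrix dens(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    shift[t] = m;
    for (int k = 0; k < K; ++k) dens(t, k) = std::exp(logdens(t, k) - m);
  }

  double ll = 0.0;
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = initprob[k] * dens(0, k); c0 += alpha(0, k); }
  if (c0 <= 0) stop("forward pass underflow at frame 0");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  scale[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * transmat(j, k);
      alpha(t, k) = s * dens(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0) stop("forward pass underflow");
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    scale[t] = ct;
  }
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]) + shift[t];

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += transmat(k, j) * dens(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / scale[t + 1];
    }
  }

  // gamma and xi
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); tot += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= tot;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * transmat(j, k) * dens(t + 1, k) *
                    beta(t + 1, k) / scale[t + 1];
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi path (1-based states) for given log-densities.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericMatrix transmat,
                          NumericVector initprob) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;
  for (int k = 0; k < K; ++k) {
    double lp = initprob[k] > 0 ? std::log(initprob[k]) : NEG;
    delta(0, k) = lp + logdens(0, k);
  }
  NumericMatrix ltrans(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltrans(j, k) = transmat(j, k) > 0 ? std::log(transmat(j, k)) : NEG;
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + ltrans(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + ltrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
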