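#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a K-state HMM.
//
// logdens: T x K state-conditional log emission densities (rows of zeros
// encode fully-missing observations). Densities are max-shifted per row
// before exponentiation, so arbitrarily small densities are handled.
//
// Returns loglik, gamma (T x K smoothed state probabilities), xi_sum
// (K x K expected transition counts) and, if want_log_ab, the log forward
// and backward variables needed for conditional-distribution diagnostics.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logdens, NumericVector pi_, NumericMatrix Gamma,
            bool want_log_ab = false) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix e(T, K), a(T, K), b(T, K), gamma(T, K), xi(K, K);
  NumericVector mx(T), logc(T);

  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int j = 1; j < K; ++j) if (logdens(t, j) > m) m = logdens(t, j);
    mx[t] = m;
    for (int j = 0; j < K; ++j) e(t, j) = std::exp(logdens(t, j) - m);
  }

  double ll = 0.0;
  {
    double c = 0.0;
    for (int j = 0; j < K; ++j) { a(0, j) = pi_[j] * e(0, j); c += a(0, j); }
    for (int j = 0; j < K; ++j) a(0, j) /= c;
    logc[0] = std::log(c);
    ll += logc[0] + mx[0];
  }
  for (int t = 1; t < T; ++t) {
    double c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += a(t - 1, k) * Gamma(k, j);
      a(t, j) = s * e(t, j);
      c += a(t, j);
    }
    for (int j = 0; j < K; ++j) a(t, j) /= c;
    logc[t] = std::log(c);
    ll += logc[t] + mx[t];
  }

  for (int j = 0; j < K; ++j) b(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double ic = std::exp(-logc[t + 1]);
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += Gamma(j, k) * e(t + 1, k) * b(t + 1, k);
      b(t, j) = s * ic;
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) { gamma(t, j) = a(t, j) * b(t, j); s += gamma(t, j); }
    for (int j = 0; j < K; ++j) gamma(t, j) /= s;
  }

  for (int t = 0; t < T - 1; ++t) {
    const double ic = std::exp(-logc[t + 1]);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += a(t, i) * Gamma(i, j) * e(t + 1, j) * b(t + 1, j) * ic;
  }

  List out = List::create(_["loglik"] = ll, _["gamma"] = gamma,
                          _["xi_sum"] = xi);
  if (want_log_ab) {
    NumericMatrix la(T, K), lb(T, K);
    double cum = 0.0;
    for (int t = 0; t < T; ++t) {
      cum += logc[t] + mx[t];
      for (int j = 0; j < K; ++j) la(t, j) = std::log(a(t, j)) + cum;
    }
    double cumb = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      for (int j = 0; j < K; ++j) lb(t, j) = std::log(b(t, j)) + cumb;
      cumb += logc[t] + mx[t];
    }
    out["log_alpha"] = la;
    out["log_beta"] = lb;
  }
  return out;
}

// Forward log likelihood only (no backward pass).
// [[Rcpp::export]]
double forward_cpp(NumericMatrix logdens, NumericVector pi_,
                   NumericMatrix Gamma) {
  const int T = logdens.nrow(), K = logdens.ncol();
  std::vector<double> prev(K), cur(K), e(K);
  double ll = 0.0;

  double m = logdens(0, 0);
  for (int j = 1; j < K; ++j) if (logdens(0, j) > m) m = logdens(0, j);
  double c = 0.0;
  for (int j = 0; j < K; ++j) {
    prev[j] = pi_[j] * std::exp(logdens(0, j) - m);
    c += prev[j];
  }
  for (int j = 0; j < K; ++j) prev[j] /= c;
  ll += std::log(c) + m;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int j = 1; j < K; ++j) if (logdens(t, j) > m) m = logdens(t, j);
    for (int j = 0; j < K; ++j) e[j] = std::exp(logdens(t, j) - m);
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += prev[k] * Gamma(k, j);
      cur[j] = s * e[j];
      c += cur[j];
    }
    for (int j = 0; j < K; ++j) prev[j] = cur[j] / c;
    ll += std::log(c) + m;
  }
  return ll;
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// Returns the 1-based most probable state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector log_pi,
                          NumericMatrix log_Gamma) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int j = 0; j < K; ++j) delta(0, j) = log_pi[j] + logdens(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      int arg = 0;
      double best = delta(t - 1, 0) + log_Gamma(0, j);
      for (int k = 1; k < K; ++k) {
        double cand = delta(t - 1, k) + log_Gamma(k, j);
        if (cand > best) { best = cand; arg = k; }  // strict: ties keep lower k
      }
      delta(t, j) = best + logdens(t, j);
      psi(t, j) = arg;
    }

  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
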