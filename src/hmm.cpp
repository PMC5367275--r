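// Two-state Poisson HMM: scaled forward-backward, Baum-Welch, Viterbi.
// States follow the package convention: column/index 1 = "active", 2 = "rest"
// once a model has been canonicalized; the recursions themselves are generic
// in the number of states.
#include <Rcpp.h>
using namespace Rcpp;

static inline double pois_logpmf(int k, double lambda) {
  if (lambda <= 0.0) return (k == 0) ? 0.0 : R_NegInf;
  return R::dpois(k, lambda, 1);
}

// Scaled forward-backward. Returns log-likelihood, per-bin posteriors
// (gamma), and the expected transition-count matrix (xi summed over t) that
// Baum-Welch needs. Scaling makes underflow impossible for arbitrarily long
// chains.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(IntegerVector counts, NumericVector init,
                          NumericMatrix trans, NumericVector rates) {
  const int T = counts.size();
  const int S = rates.size();
  NumericMatrix logb(T, S), alpha(T, S), beta(T, S), gamma(T, S);
  NumericVector cscale(T), shift(T);

  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int j = 0; j < S; ++j) {
      logb(t, j) = pois_logpmf(counts[t], rates[j]);
      if (logb(t, j) > mx) mx = logb(t, j);
    }
    if (!R_finite(mx)) {
      return List::create(_["loglik"] = R_NegInf);
    }
    shift[t] = mx;
  }

  // forward
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int j = 0; j < S; ++j) {
      double pred;
      if (t == 0) {
        pred = init[j];
      } else {
        pred = 0.0;
        for (int i = 0; i < S; ++i) pred += alpha(t - 1, i) * trans(i, j);
      }
      alpha(t, j) = pred * std::exp(logb(t, j) - shift[t]);
      norm += alpha(t, j);
    }
    if (norm <= 0.0) return List::create(_["loglik"] = R_NegInf);
    for (int j = 0; j < S; ++j) alpha(t, j) /= norm;
    cscale[t] = norm;
    loglik += std::log(norm) + shift[t];
  }

  // backward (scaled by the forward constants)
  for (int j = 0; j < S; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j)
        s += trans(i, j) * std::exp(logb(t + 1, j) - shift[t + 1]) * beta(t + 1, j);
      beta(t, i) = s / cscale[t + 1];
    }
  }

  // posteriors and expected transition counts
  NumericMatrix xi(S, S);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int j = 0; j < S; ++j) {
      gamma(t, j) = alpha(t, j) * beta(t, j);
      norm += gamma(t, j);
    }
    for (int j = 0; j < S; ++j) gamma(t, j) /= norm;
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < S; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) *
                    std::exp(logb(t + 1, j) - shift[t + 1]) * beta(t + 1, j) /
                    cscale[t + 1];
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// One full Baum-Welch run from the supplied starting values. The likelihood
// trace is returned so callers can assert EM monotonicity.
// [[Rcpp::export(name = ".hmm_em")]]
List hmm_em(IntegerVector counts, NumericVector init, NumericMatrix trans,
            NumericVector rates, double tol, int max_iter) {
  const int T = counts.size();
  const int S = rates.size();
  NumericVector pi_(clone(init)), lam(clone(rates));
  NumericMatrix A(clone(trans));
  std::vector<double> trace;
  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    List fb = hmm_forward_backward(counts, pi_, A, lam);
    ll = as<double>(fb["loglik"]);
    if (!R_finite(ll)) break;
    trace.push_back(ll);
    if (iter > 0) {
      double rel = std::fabs(ll - ll_old) / (std::fabs(ll_old) + 1e-12);
      if (rel < tol) { converged = true; break; }
    }
    ll_old = ll;
    NumericMatrix gamma = fb["gamma"], xi = fb["xi"];
    for (int j = 0; j < S; ++j) pi_[j] = gamma(0, j);
    for (int i = 0; i < S; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < S; ++j) rowsum += xi(i, j);
      for (int j = 0; j < S; ++j)
        A(i, j) = rowsum > 0 ? xi(i, j) / rowsum : 1.0 / S;
    }
    for (int j = 0; j < S; ++j) {
      double num = 0.0, den = 0.0;
      for (int t = 0; t < T; ++t) {
        num += gamma(t, j) * counts[t];
        den += gamma(t, j);
      }
      lam[j] = den > 0 ? num / den : 0.0;
    }
  }

  return List::create(_["init"] = pi_, _["trans"] = A, _["rates"] = lam,
                      _["loglik"] = ll, _["trace"] = wrap(trace),
                      _["n_iter"] = iter, _["converged"] = converged);
}

// Global decoding. Ties are broken toward the higher state index; with the
// package's (active, rest) ordering that prefers "rest", the conservative
// choice for awakening detection.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(IntegerVector counts, NumericVector init,
                          NumericMatrix trans, NumericVector rates) {
  const int T = counts.size();
  const int S = rates.size();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);

  for (int j = 0; j < S; ++j) {
    double lp = init[j] > 0 ? std::log(init[j]) : R_NegInf;
    delta(0, j) = lp + pois_logpmf(counts[0], rates[j]);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf; int arg = S - 1;
      for (int i = S - 1; i >= 0; --i) {  // scan high→low so ties keep rest
        double lt = trans(i, j) > 0 ? std::log(trans(i, j)) : R_NegInf;
        double cand = delta(t - 1, i) + lt;
        if (cand > best) { best = cand; arg = i; }
      }
      delta(t, j) = best + pois_logpmf(counts[t], rates[j]);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = S - 1;
  for (int j = S - 1; j >= 0; --j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  if (!R_finite(best)) stop("all paths have zero probability");
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices for R
}
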