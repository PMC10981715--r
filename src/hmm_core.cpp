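#include <Rcpp.h>
using namespace Rcpp;

// Core dynamic-programming recursions for the non-homogeneous two-state HMM.
// Fragments are concatenated: obs rows ordered by fragment; frag_ptr holds
// 0-based start offsets of each fragment plus a terminal sentinel (length F+1).
// States are indexed 0 = U (unmethylated), 1 = M (methylated).
// Transition matrices are distance-binned: dist_bin[t] gives the (1-based) bin
// of the distance from observation t-1 to t within a fragment (ignored at t=0).
// Initiation vectors are offset-binned per fragment: off_bin (1-based, per frag).

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log(exp(a - m) + exp(b - m));
}

static inline double log_dnorm(double x, double mu, double var) {
  double d = x - mu;
  return -0.5 * (log(2.0 * M_PI * var) + d * d / var);
}

// log emission density per observation per state:
// sum over features of log[(1-pi) N(mu1, var1) + pi N(mu2, var2)]
// pi_, mu1, mu2, var1, var2 are (2 states x nfeat) matrices.
// [[Rcpp::export]]
NumericMatrix nhmm_logemis(NumericMatrix obs, NumericMatrix pi_,
                           NumericMatrix mu1, NumericMatrix mu2,
                           NumericMatrix var1, NumericMatrix var2) {
  int n = obs.nrow(), nf = obs.ncol();
  NumericMatrix out(n, 2);
  for (int s = 0; s < 2; ++s) {
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      for (int f = 0; f < nf; ++f) {
        double x = obs(t, f);
        if (!R_finite(x)) stop("non-finite feature value at observation %d", t + 1);
        double p = pi_(s, f);
        double l1 = (p >= 1.0) ? R_NegInf : log(1.0 - p) + log_dnorm(x, mu1(s, f), var1(s, f));
        double l2 = (p <= 0.0) ? R_NegInf : log(p) + log_dnorm(x, mu2(s, f), var2(s, f));
        acc += logsumexp2(l1, l2);
      }
      out(t, s) = acc;
    }
  }
  return out;
}

// Forward-backward E-step over all fragments.
// log_init: (n_off_bins x 2); log_trans: flattened (n_dist_bins x 2 x 2),
// element (b, i, j) at b + nb*(i + 2*j) [column-major array semantics].
// Returns total and per-fragment log-likelihood, posterior state probabilities
// (gamma), expected transition counts per distance bin, and expected initial
// state counts per offset bin.
// [[Rcpp::export]]
List nhmm_estep(NumericMatrix logemis, IntegerVector frag_ptr,
                IntegerVector off_bin, IntegerVector dist_bin,
                NumericMatrix log_init, NumericVector log_trans,
                int n_dist_bins) {
  int F = frag_ptr.size() - 1;
  int n = logemis.nrow();
  NumericMatrix gamma(n, 2);
  NumericVector ll_frag(F);
  NumericVector trans_counts(n_dist_bins * 4);
  NumericMatrix init_counts(log_init.nrow(), 2);
  std::vector<double> alpha(2 * n), beta(2 * n);
  double total = 0.0;
  int nb = n_dist_bins;

  for (int f = 0; f < F; ++f) {
    int a = frag_ptr[f], b = frag_ptr[f + 1];
    int L = b - a;
    if (L <= 0) stop("empty fragment in E-step");
    int ob = off_bin[f] - 1;
    // forward
    for (int s = 0; s < 2; ++s)
      alpha[2 * a + s] = log_init(ob, s) + logemis(a, s);
    for (int t = a + 1; t < b; ++t) {
      int db = dist_bin[t] - 1;
      for (int s = 0; s < 2; ++s) {
        double acc = R_NegInf;
        for (int r = 0; r < 2; ++r)
          acc = logsumexp2(acc, alpha[2 * (t - 1) + r] + log_trans[db + nb * (r + 2 * s)]);
        alpha[2 * t + s] = acc + logemis(t, s);
      }
    }
    double ll = logsumexp2(alpha[2 * (b - 1)], alpha[2 * (b - 1) + 1]);
    if (!R_finite(ll)) stop("non-finite fragment log-likelihood (fragment %d)", f + 1);
    ll_frag[f] = ll;
    total += ll;
    // backward
    beta[2 * (b - 1)] = 0.0; beta[2 * (b - 1) + 1] = 0.0;
    for (int t = b - 2; t >= a; --t) {
      int db = dist_bin[t + 1] - 1;
      for (int s = 0; s < 2; ++s) {
        double acc = R_NegInf;
        for (int r = 0; r < 2; ++r)
          acc = logsumexp2(acc, log_trans[db + nb * (s + 2 * r)] +
                                 logemis(t + 1, r) + beta[2 * (t + 1) + r]);
        beta[2 * t + s] = acc;
      }
    }
    // gamma and expected counts
    for (int t = a; t < b; ++t)
      for (int s = 0; s < 2; ++s)
        gamma(t, s) = exp(alpha[2 * t + s] + beta[2 * t + s] - ll);
    for (int s = 0; s < 2; ++s) init_counts(ob, s) += gamma(a, s);
    for (int t = a + 1; t < b; ++t) {
      int db = dist_bin[t] - 1;
      for (int r = 0; r < 2; ++r)
        for (int s = 0; s < 2; ++s)
          trans_counts[db + nb * (r + 2 * s)] +=
            exp(alpha[2 * (t - 1) + r] + log_trans[db + nb * (r + 2 * s)] +
                logemis(t, s) + beta[2 * t + s] - ll);
    }
  }
  trans_counts.attr("dim") = IntegerVector::create(nb, 2, 2);
  return List::create(_["loglik"] = total, _["ll_frag"] = ll_frag,
                      _["gamma"] = gamma, _["trans_counts"] = trans_counts,
                      _["init_counts"] = init_counts);
}

// Viterbi decoding over all fragments. Ties are broken toward the state of the
// previous CpG on the path; at the first CpG, and for the terminal argmax,
// toward M (state index 1).
// [[Rcpp::export]]
IntegerVector nhmm_viterbi(NumericMatrix logemis, IntegerVector frag_ptr,
                           IntegerVector off_bin, IntegerVector dist_bin,
                           NumericMatrix log_init, NumericVector log_trans,
                           int n_dist_bins) {
  int F = frag_ptr.size() - 1;
  int n = logemis.nrow();
  IntegerVector path(n);
  std::vector<double> delta(2 * n);
  std::vector<int> psi(2 * n);
  int nb = n_dist_bins;

  for (int f = 0; f < F; ++f) {
    int a = frag_ptr[f], b = frag_ptr[f + 1];
    int ob = off_bin[f] - 1;
    for (int s = 0; s < 2; ++s)
      delta[2 * a + s] = log_init(ob, s) + logemis(a, s);
    for (int t = a + 1; t < b; ++t) {
      int db = dist_bin[t] - 1;
      for (int s = 0; s < 2; ++s) {
        double v0 = delta[2 * (t - 1)] + log_trans[db + nb * (0 + 2 * s)];
        double v1 = delta[2 * (t - 1) + 1] + log_trans[db + nb * (1 + 2 * s)];
        int best;
        if (v0 == v1) best = s;        // tie: continue from same state
        else best = (v1 > v0) ? 1 : 0;
        psi[2 * t + s] = best;
        delta[2 * t + s] = (best == 1 ? v1 : v0) + logemis(t, s);
      }
    }
    int last = (delta[2 * (b - 1) + 1] >= delta[2 * (b - 1)]) ? 1 : 0;
    path[b - 1] = last;
    for (int t = b - 1; t > a; --t) {
      last = psi[2 * t + last];
      path[t - 1] = last;
    }
  }
  return path + 1;  // 1-based: 1 = U, 2 = M
}
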