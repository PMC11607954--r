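#include <Rcpp.h>
using namespace Rcpp;

// Duration-dependent Viterbi decoding for a hidden semi-Markov model whose
// states follow a fixed cycle 0 -> 1 -> 2 -> ... -> S-1 -> 0 (here
// S1 -> systole -> S2 -> diastole). Emission log-likelihoods are supplied
// per frame and state; state durations have explicit log-pmfs truncated at
// a per-state maximum. Returns the maximum-likelihood state per frame
// (1-based, to match R factor levels).
//
// loglik: T x S emission log-likelihood matrix
// logdur: S x Dmax duration log-pmf matrix (row s, column d = duration d
//         frames); entries beyond a state's cap are -Inf
// [[Rcpp::export]]
IntegerVector viterbi_hsmm_cpp(NumericMatrix loglik, NumericMatrix logdur) {
  const int T = loglik.nrow();
  const int S = loglik.ncol();
  const int Dmax = logdur.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  if (T == 0) return IntegerVector(0);

  // cumulative emission log-likelihood per state: C(t, s) = sum_{u<=t} ll(u, s)
  std::vector<double> cum((T + 1) * S, 0.0);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t)
      cum[(t + 1) * S + s] = cum[t * S + s] + loglik(t, s);

  std::vector<double> delta((T + 1) * S, NEG);
  std::vector<int> best_d((T + 1) * S, 0);
  const double log_init = -std::log((double)S);

  for (int t = 1; t <= T; ++t) {
    for (int s = 0; s < S; ++s) {
      const int prev = (s + S - 1) % S;
      double best = NEG;
      int bd = 0;
      const int dmax = std::min(t, Dmax);
      for (int d = 1; d <= dmax; ++d) {
        const double ld = logdur(s, d - 1);
        if (ld == NEG) continue;
        const double emit = cum[t * S + s] - cum[(t - d) * S + s];
        const double before = (t - d == 0) ? log_init : delta[(t - d) * S + prev];
        if (before == NEG) continue;
        const double score = before + ld + emit;
        if (score > best) { best = score; bd = d; }
      }
      delta[t * S + s] = best;
      best_d[t * S + s] = bd;
    }
  }

  // terminate in the best state at T, then backtrack complete segments
  int s_end = 0;
  double best_end = NEG;
  for (int s = 0; s < S; ++s)
    if (delta[T * S + s] > best_end) { best_end = delta[T * S + s]; s_end = s; }

  IntegerVector path(T);
  if (best_end == NEG) {  // pathological input: flat fallback
    for (int t = 0; t < T; ++t) path[t] = 1;
    return path;
  }
  int t = T, s = s_end;
  while (t > 0) {
    int d = best_d[t * S + s];
    if (d <= 0) d = 1;  // should not happen; guard against stalls
    for (int u = t - d; u < t; ++u) path[u] = s + 1;
    t -= d;
    s = (s + S - 1) % S;
  }
  return path;
}
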