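#include <Rcpp.h>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Embedded-chain Monte Carlo for the birth-death process.
//
// Each simulated event is conditioned on being state-changing: a replacement
// across the invader/resident frontier.  At a resident j the invasion rate
// is r * sum_{i in S, i~j} 1/d_i; at an invader j the recovery rate is
// sum_{i not in S, i~j} 1/d_i.  Absorption probabilities are identical to
// the full chain's, with far fewer sampled events.
//
// Uses R's RNG stream (unif_rand), so results are reproducible under
// set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_mc_trials(IntegerMatrix edges, int N, double r, int trials,
                  int start) {
  if (r < 0) stop("fitness r must be nonnegative");
  std::vector<std::vector<int>> adj(N);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  std::vector<double> invw(N); // 1/d contributions
  for (int i = 0; i < N; ++i) {
    if (adj[i].empty()) stop("isolated vertex %d", i);
  }
  std::vector<double> wdeg(N);
  for (int i = 0; i < N; ++i) wdeg[i] = 1.0 / adj[i].size();

  std::vector<char> inS(N);
  std::vector<double> inv_nbr(N), res_nbr(N); // frontier weights at each vertex
  std::vector<double> act(N);

  int fixations = 0;
  for (int t = 0; t < trials; ++t) {
    int s0 = start >= 0 ? start : (int)(unif_rand() * N);
    if (s0 >= N) s0 = N - 1;
    std::fill(inS.begin(), inS.end(), 0);
    inS[s0] = 1;
    int count = 1;
    // inv_nbr[j]: sum of 1/d_i over invader neighbors i of j
    for (int j = 0; j < N; ++j) {
      double iw = 0, rw = 0;
      for (int i : adj[j]) (inS[i] ? iw : rw) += wdeg[i];
      inv_nbr[j] = iw;
      res_nbr[j] = rw;
    }
    while (count > 0 && count < N) {
      double total = 0;
      for (int j = 0; j < N; ++j) {
        act[j] = inS[j] ? res_nbr[j] : r * inv_nbr[j];
        total += act[j];
      }
      if (total <= 0) break; // r == 0 with no invader frontier outflow: extinction stalls cannot happen (losses stay positive)
      double u = unif_rand() * total;
      int j = 0;
      for (; j < N - 1; ++j) {
        u -= act[j];
        if (u <= 0) break;
      }
      // flip j
      double d = inS[j] ? -wdeg[j] : wdeg[j];
      inS[j] = !inS[j];
      count += inS[j] ? 1 : -1;
      for (int tgt : adj[j]) {
        inv_nbr[tgt] += d;
        res_nbr[tgt] -= d;
      }
    }
    if (count == N) ++fixations;
  }
  return fixations;
}
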