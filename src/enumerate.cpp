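#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <functional>
#include <set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Canonical labeling of small graphs and exhaustive connected enumeration.
//
// The canonical key of a graph is the lexicographically minimal upper-
// triangle adjacency bit-string over a set of vertex orderings.  Two keys
// are provided:
//   * full  — minimum over all N! orderings (the brute-force definition;
//             used as an oracle for N <= 5),
//   * refined — minimum over orderings compatible with Weisfeiler–Leman
//             style vertex-invariant classes.  The classes are isomorphism
//             invariants, so the refined key induces the same equivalence
//             as the full key while being far cheaper for N = 6, 7.
// ---------------------------------------------------------------------------

struct SmallGraph {
  int N;
  std::vector<uint32_t> adj; // adjacency bitmask rows
};

static SmallGraph from_edges(const IntegerMatrix &edges, int N) {
  SmallGraph g;
  g.N = N;
  g.adj.assign(N, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a < 0 || b < 0 || a >= N || b >= N || a == b) stop("bad edge");
    g.adj[a] |= 1u << b;
    g.adj[b] |= 1u << a;
  }
  return g;
}

static bool connected_mask(const SmallGraph &g) {
  uint32_t seen = 1, frontier = 1;
  while (frontier) {
    uint32_t nxt = 0;
    for (int v = 0; v < g.N; ++v)
      if (frontier & (1u << v)) nxt |= g.adj[v];
    frontier = nxt & ~seen;
    seen |= nxt;
  }
  return seen == (uint32_t)((1u << g.N) - 1);
}

// upper-triangle bit-string under ordering perm (perm[pos] = original vertex)
static uint64_t key_under(const SmallGraph &g, const std::vector<int> &perm) {
  uint64_t key = 0;
  int bit = 0;
  for (int i = 0; i < g.N; ++i)
    for (int j = i + 1; j < g.N; ++j, ++bit)
      if (g.adj[perm[i]] & (1u << perm[j])) key |= 1ull << bit;
  return key;
}

static uint64_t canonical_full(const SmallGraph &g) {
  std::vector<int> perm(g.N);
  for (int i = 0; i < g.N; ++i) perm[i] = i;
  uint64_t best = UINT64_MAX;
  do {
    best = std::min(best, key_under(g, perm));
  } while (std::next_permutation(perm.begin(), perm.end()));
  return best;
}

// iterated degree refinement: rank vertices by an isomorphism-invariant
// signature, then minimize only over class-preserving orderings
static std::vector<int> wl_ranks(const SmallGraph &g) {
  std::vector<int> rank(g.N, 0);
  for (int round = 0; round < g.N; ++round) {
    std::vector<std::pair<std::vector<int>, int>> sig(g.N);
    for (int v = 0; v < g.N; ++v) {
      std::vector<int> s = {rank[v]};
      std::vector<int> nb;
      for (int w = 0; w < g.N; ++w)
        if (g.adj[v] & (1u << w)) nb.push_back(rank[w]);
      std::sort(nb.begin(), nb.end());
      s.insert(s.end(), nb.begin(), nb.end());
      sig[v] = {s, v};
    }
    std::vector<std::pair<std::vector<int>, int>> sorted = sig;
    std::sort(sorted.begin(), sorted.end());
    std::vector<int> newrank(g.N);
    int rk = 0;
    for (int i = 0; i < g.N; ++i) {
      if (i > 0 && sorted[i].first != sorted[i - 1].first) ++rk;
      newrank[sorted[i].second] = rk;
    }
    if (newrank == rank) break;
    rank = newrank;
  }
  return rank;
}

static uint64_t canonical_refined(const SmallGraph &g) {
  std::vector<int> rank = wl_ranks(g);
  // vertices grouped by rank, classes in ascending rank order
  std::vector<std::vector<int>> classes;
  int maxr = *std::max_element(rank.begin(), rank.end());
  classes.resize(maxr + 1);
  for (int v = 0; v < g.N; ++v) classes[rank[v]].push_back(v);
  // odometer over within-class permutations
  uint64_t best = UINT64_MAX;
  std::vector<int> perm;
  std::function<void(size_t)> rec = [&](size_t ci) {
    if (ci == classes.size()) {
      best = std::min(best, key_under(g, perm));
      return;
    }
    std::vector<int> cls = classes[ci];
    std::sort(cls.begin(), cls.end());
    do {
      perm.insert(perm.end(), cls.begin(), cls.end());
      rec(ci + 1);
      perm.resize(perm.size() - cls.size());
    } while (std::next_permutation(cls.begin(), cls.end()));
  };
  rec(0);
  return best;
}

static std::string key_string(int N, uint64_t key) {
  int bits = N * (N - 1) / 2;
  std::string s = std::to_string(N);
  s += ":";
  for (int b = 0; b < bits; ++b) s += (key >> b) & 1 ? '1' : '0';
  return s;
}

// [[Rcpp::export]]
std::string cpp_canonical_key(IntegerMatrix edges, int N, bool full) {
  if (N < 1 || N > 8) stop("canonical labeling supported for 1 <= N <= 8");
  SmallGraph g = from_edges(edges, N);
  uint64_t key = full ? canonical_full(g) : canonical_refined(g);
  return key_string(N, key);
}

static IntegerMatrix key_to_edges(int N, uint64_t key) {
  std::vector<std::pair<int, int>> ed;
  int bit = 0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j, ++bit)
      if ((key >> bit) & 1) ed.push_back({i, j});
  IntegerMatrix m((int)ed.size(), 2);
  for (size_t e = 0; e < ed.size(); ++e) { m(e, 0) = ed[e].first; m(e, 1) = ed[e].second; }
  return m;
}

// [[Rcpp::export]]
List cpp_enumerate_connected(int N) {
  if (N < 2 || N > 7)
    stop("exhaustive enumeration supported for 2 <= N <= 7 (combinatorial blow-up beyond)");
  int E = N * (N - 1) / 2;
  std::set<uint64_t> canon;
  SmallGraph g;
  g.N = N;
  std::vector<std::pair<int, int>> epos;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) epos.push_back({i, j});
  for (uint64_t mask = 0; mask < (1ull << E); ++mask) {
    g.adj.assign(N, 0);
    for (int b = 0; b < E; ++b)
      if ((mask >> b) & 1) {
        g.adj[epos[b].first] |= 1u << epos[b].second;
        g.adj[epos[b].second] |= 1u << epos[b].first;
      }
    bool any_isolated = false;
    for (int v = 0; v < N; ++v) if (!g.adj[v]) { any_isolated = true; break; }
    if (any_isolated || !connected_mask(g)) continue;
    canon.insert(canonical_refined(g));
  }
  List out(canon.size());
  int i = 0;
  for (uint64_t key : canon) out[i++] = key_to_edges(N, key);
  return out;
}
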