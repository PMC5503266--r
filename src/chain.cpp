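#include <Rcpp.h>
#include "rat.h"
#include <map>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Graph plumbing: edges arrive as a 2-column 0-based integer matrix.
// ---------------------------------------------------------------------------

struct Graph {
  int N;
  std::vector<std::vector<int>> adj;
  std::vector<int> deg;
};

static Graph build_graph(const IntegerMatrix &edges, int N) {
  Graph g;
  g.N = N;
  g.adj.assign(N, {});
  std::vector<std::vector<char>> seen(N, std::vector<char>(N, 0));
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a < 0 || b < 0 || a >= N || b >= N)
      stop("edge endpoint out of range");
    if (a == b) stop("self-loop at vertex %d", a);
    if (seen[a][b]) stop("duplicate edge %d-%d", a, b);
    seen[a][b] = seen[b][a] = 1;
    g.adj[a].push_back(b);
    g.adj[b].push_back(a);
  }
  g.deg.resize(N);
  for (int i = 0; i < N; ++i) {
    g.deg[i] = (int)g.adj[i].size();
    if (g.deg[i] == 0) stop("isolated vertex %d", i);
  }
  return g;
}

static bool graph_connected(const Graph &g) {
  std::vector<char> vis(g.N, 0);
  std::vector<int> stack = {0};
  vis[0] = 1;
  int n = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int w : g.adj[v]) if (!vis[w]) { vis[w] = 1; ++n; stack.push_back(w); }
  }
  return n == g.N;
}

// [[Rcpp::export]]
bool cpp_connected(IntegerMatrix edges, int N) {
  return graph_connected(build_graph(edges, N));
}

// [[Rcpp::export]]
CharacterVector cpp_vertex_temperatures(IntegerMatrix edges, int N) {
  Graph g = build_graph(edges, N);
  CharacterVector out(N);
  for (int i = 0; i < N; ++i) {
    mpq_class t(0);
    for (int j : g.adj[i]) t += mpq_class(1, g.deg[j]);
    t.canonicalize();
    out[i] = rat_str(t);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_solve_linear(CharacterVector mat, int n, CharacterVector rhs) {
  // column-major n x n matrix, rhs length n; exported for reuse/testing
  Mat M(n, std::vector<mpq_class>(n)), B(n, std::vector<mpq_class>(1));
  for (int c = 0; c < n; ++c)
    for (int r = 0; r < n; ++r)
      M[r][c] = rat_parse(as<std::string>(mat[c * n + r]));
  for (int r = 0; r < n; ++r) B[r][0] = rat_parse(as<std::string>(rhs[r]));
  bool ok = solve_dense(M, B);
  CharacterVector x(n);
  if (ok) for (int r = 0; r < n; ++r) x[r] = rat_str(B[r][0]);
  return List::create(_["ok"] = ok, _["x"] = x);
}

// ---------------------------------------------------------------------------
// Levelled absorbing-chain solver.
//
// The birth-death chain only moves between adjacent invader-count levels,
// so ordering states by level makes the embedded-chain system block
// tridiagonal.  With Phi = 0 on the bottom level, forward elimination gives
// Phi_k = U_k Phi_{k+1} and the top level (fixation) closes the recursion
// with Phi = 1.  All arithmetic is exact rational.
//
// Input: per transient state, sparse rates down (to level k-1) and up (to
// level k+1); rates are the state-changing numerators of the kernel (the
// total-weight denominator cancels in the embedded chain).
// ---------------------------------------------------------------------------

struct SpEntry { int col; mpq_class v; };
typedef std::vector<std::vector<SpEntry>> SpMat; // rows of a level

// levels: for k = 0..L, states_per_level[k] = number of states;
// level 0 must be the single extinction state, level L the single fixation
// state.  down[k], up[k] are the sparse rate blocks for level k (1..L-1),
// rows indexed within level k, cols within level k-1 / k+1.
static std::vector<std::vector<mpq_class>> solve_levelled(
    int L, const std::vector<int> &m,
    const std::vector<SpMat> &down, const std::vector<SpMat> &up) {
  // U[k]: m[k] x m[k+1], Phi_k = U[k] Phi_{k+1}
  std::vector<Mat> U(L);
  Mat Uprev; // U[k-1]
  for (int k = 1; k < L; ++k) {
    int mk = m[k], mdown = m[k - 1], mup = m[k + 1];
    // row scaling: embedded chain divides by total rate; equivalent to
    // solving (T - A U_prev_scaled ...) -- here work with raw rates:
    // total(s) Phi_s = sum_down rate*Phi + sum_up rate*Phi
    Mat M(mk, std::vector<mpq_class>(mk, mpq_class(0)));
    Mat B(mk, std::vector<mpq_class>(mup, mpq_class(0)));
    for (int r = 0; r < mk; ++r) {
      mpq_class total(0);
      for (const auto &e : down[k][r]) total += e.v;
      for (const auto &e : up[k][r]) total += e.v;
      M[r][r] = total;
      // subtract down-rates * U[k-1]
      if (k > 1) {
        for (const auto &e : down[k][r]) {
          const std::vector<mpq_class> &urow = Uprev[e.col];
          for (int c = 0; c < mk; ++c)
            if (urow[c] != 0) M[r][c] -= e.v * urow[c];
        }
      }
      // (k == 1: down leads to extinction, Phi = 0, contributes nothing)
      for (const auto &e : up[k][r]) B[r][e.col] += e.v;
    }
    if (!solve_dense(M, B))
      stop("levelled solve: singular block at level %d", k);
    U[k] = std::move(B);
    Uprev = U[k];
  }
  // back-substitution: Phi_L = (1), Phi_k = U[k] Phi_{k+1}
  std::vector<std::vector<mpq_class>> phi(L + 1);
  phi[L] = {mpq_class(1)};
  for (int k = L - 1; k >= 1; --k) {
    phi[k].assign(m[k], mpq_class(0));
    for (int r = 0; r < m[k]; ++r) {
      mpq_class v(0);
      for (int c = 0; c < m[k + 1]; ++c)
        if (U[k][r][c] != 0) v += U[k][r][c] * phi[k + 1][c];
      phi[k][r] = v;
    }
  }
  phi[0] = {mpq_class(0)};
  return phi;
}

// ---------------------------------------------------------------------------
// Full 2^N-state chain.
// ---------------------------------------------------------------------------

// gain rate at resident j:  r * sum_{i in S, i~j} 1/d_i
// loss rate at invader j:       sum_{i notin S, i~j} 1/d_i
static void state_rates(const Graph &g, unsigned S, const mpq_class &r,
                        std::vector<std::pair<int, mpq_class>> &gains,
                        std::vector<std::pair<int, mpq_class>> &losses) {
  gains.clear(); losses.clear();
  for (int j = 0; j < g.N; ++j) {
    bool inv = (S >> j) & 1u;
    mpq_class w(0);
    for (int i : g.adj[j]) {
      bool i_inv = (S >> i) & 1u;
      if (inv != i_inv) w += mpq_class(1, g.deg[i]);
    }
    if (w == 0) continue;
    if (inv) losses.push_back({j, w});
    else { w *= r; gains.push_back({j, w}); }
  }
}

// [[Rcpp::export]]
List cpp_fixation_full(IntegerMatrix edges, int N, std::string r_str,
                       bool want_states) {
  if (N > 14) stop("full-state solve limited to N <= 14; use the lumped or Monte Carlo mode");
  Graph g = build_graph(edges, N);
  if (!graph_connected(g)) stop("graph is not connected; fixation is not well defined from every state");
  mpq_class r = rat_parse(r_str);
  if (r <= 0) stop("fitness r must be positive");

  unsigned nstates = 1u << N;
  // group states by popcount level
  std::vector<std::vector<unsigned>> level_states(N + 1);
  std::vector<unsigned> pos(nstates);
  for (unsigned S = 0; S < nstates; ++S) {
    int pc = __builtin_popcount(S);
    pos[S] = (unsigned)level_states[pc].size();
    level_states[pc].push_back(S);
  }
  std::vector<int> m(N + 1);
  for (int k = 0; k <= N; ++k) m[k] = (int)level_states[k].size();

  std::vector<SpMat> down(N + 1), up(N + 1);
  std::vector<std::pair<int, mpq_class>> gains, losses;
  for (int k = 1; k < N; ++k) {
    down[k].assign(m[k], {});
    up[k].assign(m[k], {});
    for (int ridx = 0; ridx < m[k]; ++ridx) {
      unsigned S = level_states[k][ridx];
      state_rates(g, S, r, gains, losses);
      for (auto &pr : gains)
        up[k][ridx].push_back({(int)pos[S | (1u << pr.first)], pr.second});
      for (auto &pr : losses)
        down[k][ridx].push_back({(int)pos[S & ~(1u << pr.first)], pr.second});
    }
  }
  auto phi = solve_levelled(N, m, down, up);

  CharacterVector per_vertex(N);
  mpq_class avg(0);
  for (int i = 0; i < N; ++i) {
    unsigned S = 1u << i;
    const mpq_class &v = phi[1][pos[S]];
    per_vertex[i] = rat_str(v);
    avg += v;
  }
  avg /= N;
  avg.canonicalize();
  List out = List::create(_["per_vertex"] = per_vertex,
                          _["average"] = rat_str(avg));
  if (want_states) {
    CharacterVector ps(nstates);
    for (unsigned S = 0; S < nstates; ++S)
      ps[S] = rat_str(phi[__builtin_popcount(S)][pos[S]]);
    out["per_state"] = ps;
  }
  return out;
}

// Eq-style single transition probability (self-loop included), exact.
// [[Rcpp::export]]
std::string cpp_transition_probability(IntegerMatrix edges, int N,
                                       IntegerVector S, IntegerVector S2,
                                       std::string r_str) {
  Graph g = build_graph(edges, N);
  mpq_class r = rat_parse(r_str);
  if (r <= 0) stop("fitness r must be positive");
  std::vector<char> inS(N, 0), inS2(N, 0);
  for (int v : S) { if (v < 0 || v >= N) stop("vertex out of range"); inS[v] = 1; }
  for (int v : S2) { if (v < 0 || v >= N) stop("vertex out of range"); inS2[v] = 1; }
  int nS = 0; for (int i = 0; i < N; ++i) nS += inS[i];
  mpq_class wS = r * nS + (N - nS); // total reproductive weight
  // symmetric difference
  std::vector<int> diff;
  for (int i = 0; i < N; ++i) if (inS[i] != inS2[i]) diff.push_back(i);
  mpq_class p(0);
  if (diff.size() == 1) {
    int j = diff[0];
    mpq_class w(0);
    if (!inS[j]) { // gain of j
      for (int i : g.adj[j]) if (inS[i]) w += mpq_class(1, g.deg[i]);
      p = r * w / wS;
    } else {       // loss of j
      for (int i : g.adj[j]) if (!inS[i]) w += mpq_class(1, g.deg[i]);
      p = w / wS;
    }
  } else if (diff.empty()) { // self-loop
    mpq_class win(0), wres(0);
    for (int i = 0; i < N; ++i)
      for (int j : g.adj[i]) {
        if (inS[i] && inS[j]) win += mpq_class(1, g.deg[i]);
        if (!inS[i] && !inS[j]) wres += mpq_class(1, g.deg[i]);
      }
    p = (r * win + wres) / wS;
  }
  p.canonicalize();
  return rat_str(p);
}

// ---------------------------------------------------------------------------
// Lumped chain for (possibly unbalanced) ell-graphs.
//
// Labeling convention (fixed): part A = 0..p-1, part B = p..p+q-1 (A and B
// together form the clique K_{p+q}), u = p+q (joined to A and v),
// v = p+q+1 (joined to B and u).  Orbit label: (e, k, k', e') = (u occupied,
// |S ∩ A|, |S ∩ B|, v occupied).  For p == q the swap (A,u)<->(B,v) is an
// automorphism and states are canonicalized so that (k,e) >=lex (k',e').
// ---------------------------------------------------------------------------

struct RState { int e, k, kp, ep; };

static bool rs_lt(const RState &a, const RState &b) {
  if (a.e != b.e) return a.e < b.e;
  if (a.k != b.k) return a.k < b.k;
  if (a.kp != b.kp) return a.kp < b.kp;
  return a.ep < b.ep;
}

static RState canon_rs(RState s, bool swap_sym) {
  if (swap_sym) {
    // (k,e) >=lex (k',e')
    if (s.k < s.kp || (s.k == s.kp && s.e < s.ep))
      return {s.ep, s.kp, s.k, s.e};
  }
  return s;
}

static Graph ell_graph(int p, int q) {
  int N = p + q + 2;
  std::vector<std::pair<int,int>> ed;
  for (int i = 0; i < p + q; ++i)
    for (int j = i + 1; j < p + q; ++j) ed.push_back({i, j});
  for (int i = 0; i < p; ++i) ed.push_back({i, p + q});
  for (int i = p; i < p + q; ++i) ed.push_back({i, p + q + 1});
  ed.push_back({p + q, p + q + 1});
  IntegerMatrix m((int)ed.size(), 2);
  for (size_t i = 0; i < ed.size(); ++i) { m(i,0) = ed[i].first; m(i,1) = ed[i].second; }
  return build_graph(m, N);
}

// full-state representative of an orbit, as a bitmask over p+q+2 vertices
static unsigned rs_representative(const RState &s, int p, int q) {
  unsigned S = 0;
  for (int i = 0; i < s.k; ++i) S |= 1u << i;
  for (int i = 0; i < s.kp; ++i) S |= 1u << (p + i);
  if (s.e) S |= 1u << (p + q);
  if (s.ep) S |= 1u << (p + q + 1);
  return S;
}

static RState reduce_mask(unsigned S, int p, int q, bool swap_sym) {
  RState s{0, 0, 0, 0};
  for (int i = 0; i < p; ++i) if ((S >> i) & 1u) ++s.k;
  for (int i = 0; i < q; ++i) if ((S >> (p + i)) & 1u) ++s.kp;
  s.e = (S >> (p + q)) & 1u;
  s.ep = (S >> (p + q + 1)) & 1u;
  return canon_rs(s, swap_sym);
}

struct RSpace {
  std::vector<RState> states;
  std::map<std::tuple<int,int,int,int>, int> index;
  std::vector<int> level_of;
  int find(const RState &s) const {
    auto it = index.find(std::make_tuple(s.e, s.k, s.kp, s.ep));
    return it == index.end() ? -1 : it->second;
  }
};

static RSpace reduced_space(int p, int q, bool swap_sym) {
  std::vector<RState> all;
  for (int e = 0; e <= 1; ++e)
    for (int k = 0; k <= p; ++k)
      for (int kp = 0; kp <= q; ++kp)
        for (int ep = 0; ep <= 1; ++ep) {
          RState s{e, k, kp, ep};
          RState c = canon_rs(s, swap_sym);
          if (c.e == e && c.k == k && c.kp == kp && c.ep == ep)
            all.push_back(s);
        }
  std::sort(all.begin(), all.end(), [](const RState &a, const RState &b) {
    int la = a.e + a.k + a.kp + a.ep, lb = b.e + b.k + b.kp + b.ep;
    if (la != lb) return la < lb;
    return rs_lt(a, b);
  });
  RSpace sp;
  sp.states = all;
  for (int i = 0; i < (int)all.size(); ++i) {
    sp.index[std::make_tuple(all[i].e, all[i].k, all[i].kp, all[i].ep)] = i;
    sp.level_of.push_back(all[i].e + all[i].k + all[i].kp + all[i].ep);
  }
  return sp;
}

// [[Rcpp::export]]
IntegerMatrix cpp_reduced_space(int p, int q, bool swap_sym) {
  RSpace sp = reduced_space(p, q, swap_sym);
  IntegerMatrix out((int)sp.states.size(), 4);
  for (int i = 0; i < (int)sp.states.size(); ++i) {
    out(i, 0) = sp.states[i].e; out(i, 1) = sp.states[i].k;
    out(i, 2) = sp.states[i].kp; out(i, 3) = sp.states[i].ep;
  }
  colnames(out) = CharacterVector::create("e", "k", "kp", "ep");
  return out;
}

// lumped one-step transition row from canonical state s (Eq-kernel
// probabilities, self-loop included): rate to each target orbit.
// [[Rcpp::export]]
List cpp_lumped_row(int p, int q, bool swap_sym, IntegerVector s4,
                    std::string r_str) {
  mpq_class r = rat_parse(r_str);
  if (r <= 0) stop("fitness r must be positive");
  Graph g = ell_graph(p, q);
  int N = g.N;
  RState s{s4[0], s4[1], s4[2], s4[3]};
  RState c = canon_rs(s, swap_sym);
  if (c.e != s.e || c.k != s.k || c.kp != s.kp || c.ep != s.ep)
    stop("state is not canonical");
  unsigned S = rs_representative(s, p, q);
  int nS = __builtin_popcount(S);
  mpq_class wS = r * nS + (N - nS);

  std::map<std::tuple<int,int,int,int>, mpq_class> acc;
  std::vector<std::pair<int, mpq_class>> gains, losses;
  state_rates(g, S, r, gains, losses);
  mpq_class moved(0);
  auto add = [&](unsigned T, mpq_class pr) {
    RState t = reduce_mask(T, p, q, swap_sym);
    acc[std::make_tuple(t.e, t.k, t.kp, t.ep)] += pr;
    moved += pr;
  };
  if (nS != 0 && nS != N) {
    for (auto &pr : gains) add(S | (1u << pr.first), pr.second / wS);
    for (auto &pr : losses) add(S & ~(1u << pr.first), pr.second / wS);
  }
  // self-loop = remaining mass
  acc[std::make_tuple(s.e, s.k, s.kp, s.ep)] += 1 - moved;

  int n = (int)acc.size();
  IntegerMatrix targets(n, 4);
  CharacterVector probs(n);
  int i = 0;
  for (auto &kv : acc) {
    targets(i, 0) = std::get<0>(kv.first); targets(i, 1) = std::get<1>(kv.first);
    targets(i, 2) = std::get<2>(kv.first); targets(i, 3) = std::get<3>(kv.first);
    mpq_class v = kv.second; v.canonicalize();
    probs[i] = rat_str(v);
    ++i;
  }
  colnames(targets) = CharacterVector::create("e", "k", "kp", "ep");
  return List::create(_["targets"] = targets, _["prob"] = probs);
}

// [[Rcpp::export]]
List cpp_reduced_fixation(int p, int q, bool swap_sym, std::string r_str) {
  mpq_class r = rat_parse(r_str);
  if (r <= 0) stop("fitness r must be positive");
  Graph g = ell_graph(p, q);
  int N = g.N;
  RSpace sp = reduced_space(p, q, swap_sym);
  int M = (int)sp.states.size();

  // per-level layout
  std::vector<std::vector<int>> level_states(N + 1);
  std::vector<int> pos(M);
  for (int i = 0; i < M; ++i) {
    pos[i] = (int)level_states[sp.level_of[i]].size();
    level_states[sp.level_of[i]].push_back(i);
  }
  std::vector<int> m(N + 1);
  for (int k = 0; k <= N; ++k) m[k] = (int)level_states[k].size();
  if (m[0] != 1 || m[N] != 1) stop("internal: absorbing levels malformed");

  std::vector<SpMat> down(N + 1), up(N + 1);
  std::vector<std::pair<int, mpq_class>> gains, losses;
  for (int k = 1; k < N; ++k) {
    down[k].assign(m[k], {});
    up[k].assign(m[k], {});
    for (int ridx = 0; ridx < m[k]; ++ridx) {
      const RState &s = sp.states[level_states[k][ridx]];
      unsigned S = rs_representative(s, p, q);
      state_rates(g, S, r, gains, losses);
      std::map<int, mpq_class> accu, accd;
      for (auto &pr : gains) {
        RState t = reduce_mask(S | (1u << pr.first), p, q, swap_sym);
        accu[sp.find(t)] += pr.second;
      }
      for (auto &pr : losses) {
        RState t = reduce_mask(S & ~(1u << pr.first), p, q, swap_sym);
        accd[sp.find(t)] += pr.second;
      }
      for (auto &kv : accu) up[k][ridx].push_back({pos[kv.first], kv.second});
      for (auto &kv : accd) down[k][ridx].push_back({pos[kv.first], kv.second});
    }
  }
  auto phi = solve_levelled(N, m, down, up);

  CharacterVector per_orbit(M);
  for (int i = 0; i < M; ++i)
    per_orbit[i] = rat_str(phi[sp.level_of[i]][pos[i]]);

  // uniform single-invader average over the N vertices
  auto orbit_phi = [&](RState t) -> mpq_class {
    t = canon_rs(t, swap_sym);
    int i = sp.find(t);
    return phi[sp.level_of[i]][pos[i]];
  };
  mpq_class avg = mpq_class(p) * orbit_phi({0, 1, 0, 0})
                + mpq_class(q) * orbit_phi({0, 0, 1, 0})
                + orbit_phi({1, 0, 0, 0}) + orbit_phi({0, 0, 0, 1});
  avg /= N;
  avg.canonicalize();

  IntegerMatrix states = cpp_reduced_space(p, q, swap_sym);
  return List::create(_["average"] = rat_str(avg),
                      _["per_orbit"] = per_orbit,
                      _["states"] = states);
}
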