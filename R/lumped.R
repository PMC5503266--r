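#' Orbit label of an invader set on an ell-graph
#'
#' Under the automorphisms of the (possibly unbalanced) ell-graph —
#' permutations within each clique part, plus the `(A,u) <-> (B,v)` swap in
#' the balanced case — an invader set is determined up to symmetry by the
#' 4-tuple `(e, k, k', e')`: occupancy of extra vertex `u`, invader count in
#' its part A, invader count in part B, occupancy of `v`.  In the balanced
#' case the representative is canonicalized so that `(k, e) >= (k', e')`
#' lexicographically.
#'
#' @param n half-size of the balanced ell-graph (so `p = q = n`); ignored
#'   when `p`, `q` are given.
#' @param S invader set as 0-based vertex ids under the package's ell-graph
#'   labeling (A = `0..p-1`, B = `p..p+q-1`, `u = p+q`, `v = p+q+1`).
#' @param p,q clique part sizes for unbalanced variants (no swap symmetry
#'   unless `p == q`).
#' @return named integer vector `c(e, k, kp, ep)`.
#' @examples
#' reduce_state(2, c(0, 5))  # one A-vertex plus extra vertex v: c(0, 1, 0, 1)
#' @export
reduce_state <- function(n, S, p = NULL, q = NULL) {
  pq <- resolve_pq(n, p, q)
  p <- pq[1]; q <- pq[2]
  S <- unique(as.integer(S))
  if (anyNA(S) || any(S < 0) || any(S > p + q + 1L)) stop("vertex id outside the ell-graph")
  s <- c(e = as.integer((p + q) %in% S),
         k = sum(S < p),
         kp = sum(S >= p & S < p + q),
         ep = as.integer((p + q + 1L) %in% S))
  canonicalize_rstate(s, swap = p == q)
}

canonicalize_rstate <- function(s, swap) {
  if (swap) {
    # canonical iff (k, e) >=lex (k', e')
    if (s[["k"]] < s[["kp"]] || (s[["k"]] == s[["kp"]] && s[["e"]] < s[["ep"]])) {
      s <- c(e = s[["ep"]], k = s[["kp"]], kp = s[["k"]], ep = s[["e"]])
    }
  }
  s
}

resolve_pq <- function(n, p, q) {
  if (is.null(p) != is.null(q)) stop("give both p and q, or neither")
  if (is.null(p)) {
    n <- as.integer(n)
    if (is.na(n) || n < 2) stop("invalid order: need n >= 2")
    c(n, n)
  } else {
    p <- as.integer(p); q <- as.integer(q)
    if (is.na(p) || is.na(q) || p < 1 || q < 1) stop("invalid order: need p, q >= 1")
    c(p, q)
  }
}

#' Reduced state space of the lumped ell-graph chain
#'
#' All canonical orbit labels `(e, k, k', e')`, ordered deterministically by
#' total invader count and then lexicographically.  For the balanced
#' ell-graph of order `N = 2n + 2` there are exactly `N(N+1)/2` of them
#' (21, 36, 55 for orders 6, 8, 10) — versus `2^N` full states.
#'
#' @inheritParams reduce_state
#' @return data.frame with integer columns `e, k, kp, ep`.
#' @export
reduced_state_space <- function(n, p = NULL, q = NULL) {
  pq <- resolve_pq(n, p, q)
  m <- cpp_reduced_space(pq[1], pq[2], pq[1] == pq[2])
  as.data.frame(m)
}

#' Lumped one-step transition probability
#'
#' Probability of moving between orbit states in one step of the lumped
#' chain: the sum of full-chain transition probabilities from any fixed
#' representative of `s` to all members of the orbit of `s2`.  Well defined
#' (independent of the representative) because the orbit partition is
#' induced by graph automorphisms, which makes the chain strongly lumpable.
#' Self-loops are included, so each row sums to 1.
#'
#' @inheritParams reduce_state
#' @param s,s2 canonical orbit states, as length-4 integer vectors
#'   `(e, k, kp, ep)`.
#' @param r fitness.
#' @return canonical rational string.
#' @export
lumped_transition <- function(n, s, s2, r, p = NULL, q = NULL) {
  pq <- resolve_pq(n, p, q)
  row <- lumped_transition_row(n, s, r, p = pq[1], q = pq[2])
  s2 <- as.integer(s2)
  hit <- row$targets[, "e"] == s2[1] & row$targets[, "k"] == s2[2] &
    row$targets[, "kp"] == s2[3] & row$targets[, "ep"] == s2[4]
  if (any(hit)) row$prob[which(hit)] else "0"
}

#' @rdname lumped_transition
#' @return `lumped_transition_row()`: list with the reachable `targets`
#'   (integer matrix) and their exact probabilities `prob`.
#' @export
lumped_transition_row <- function(n, s, r, p = NULL, q = NULL) {
  pq <- resolve_pq(n, p, q)
  s <- as.integer(s)
  if (length(s) != 4) stop("state must be (e, k, kp, ep)")
  cpp_lumped_row(pq[1], pq[2], pq[1] == pq[2], s, as_rational(r))
}

#' Exact fixation probability via the symmetry-lumped chain
#'
#' Solves the lumped absorbing chain on the `(e, k, k', e')` orbit states
#' exactly; for the balanced ell-graph of order `N` this is `N(N+1)/2`
#' states instead of `2^N`, with identical fixation probabilities (strong
#' lumpability under the automorphism group).  The average is over a
#' uniformly random single-invader start, i.e. weight `p : q : 1 : 1` on the
#' orbits of an A-clique, B-clique, `u` and `v` start.
#'
#' @inheritParams reduce_state
#' @param r fitness, positive.
#' @param per_orbit also return the fixation probability of every orbit.
#' @return canonical rational string, or (with `per_orbit`) a list with
#'   `average`, `per_orbit`, `states`.
#' @examples
#' reduced_fixation(2, 1)     # "1/6": neutral drift on 6 vertices
#' @export
reduced_fixation <- function(n, r, p = NULL, q = NULL, per_orbit = FALSE) {
  pq <- resolve_pq(n, p, q)
  r <- as_rational(r)
  if (rat_cmp(r, 0L) <= 0) stop("fitness r must be positive")
  res <- cpp_reduced_fixation(pq[1], pq[2], pq[1] == pq[2], r)
  if (per_orbit) {
    list(average = res$average, per_orbit = res$per_orbit,
         states = as.data.frame(res$states))
  } else {
    res$average
  }
}
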