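# Independent oracles used across the suite.

expect_rat_equal <- function(a, b) {
  expect_identical(as_rational(a), as_rational(b))
}

# Numeric fixation oracle, independent of the exact solver's code path:
# build the full 2^N one-step kernel from transition_probability() (the
# direct four-case formula, self-loops included) and solve the absorbing
# system in floating point with base R's solve().
numeric_fixation_oracle <- function(g, r) {
  N <- g$n_vertices
  states <- 0:(2^N - 1)
  members <- lapply(states, function(s) which(bitwAnd(s, 2^(0:(N - 1))) > 0) - 1L)
  n_states <- length(states)
  P <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    S <- members[[i]]
    # only self, gain-one and lose-one targets can be nonzero
    targets <- c(i, which(vapply(members, function(T)
      length(union(setdiff(S, T), setdiff(T, S))) == 1L, NA)))
    for (j in targets) {
      P[i, j] <- rat_num(transition_probability(g, S, members[[j]], r))
    }
  }
  transient <- 2:(n_states - 1) # all but empty set and full set
  Q <- P[transient, transient, drop = FALSE]
  b <- P[transient, n_states]
  phi <- solve(diag(length(transient)) - Q, b)
  singletons <- match(2^(0:(N - 1)), states)
  mean(c(0, phi, 1)[singletons]) # phi over all states incl. absorbing, pick singletons
}

# Brute-force isomorphism-class oracle for tiny orders: scan every labeled
# graph, keep the connected ones, and deduplicate by the full N!-permutation
# canonical key.
bruteforce_connected_classes <- function(N) {
  pairs <- t(combn(0:(N - 1), 2))
  E <- nrow(pairs)
  keys <- character(0)
  for (mask in 0:(2^E - 1)) {
    sel <- bitwAnd(mask, 2^(0:(E - 1))) > 0
    if (!any(sel)) next
    edges <- pairs[sel, , drop = FALSE]
    deg <- tabulate(edges + 1L, nbins = N)
    if (any(deg == 0)) next
    g <- moran_graph(edges, N)
    if (!is_connected(g)) next
    keys <- c(keys, canonical_form(g, full = TRUE))
  }
  sort(unique(keys))
}

# ell-graph built from scratch by its definition, independently of
# make_unbalanced_ell(): K_{p+q} plus u joined to the p-part and v, v joined
# to the q-part and u.
ell_edges_by_hand <- function(p, q) {
  cl <- t(combn(0:(p + q - 1), 2))
  rbind(cl,
        cbind(0:(p - 1), p + q),
        cbind(p + 0:(q - 1), p + q + 1),
        c(p + q, p + q + 1))
}
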