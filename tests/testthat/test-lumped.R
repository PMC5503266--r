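test_that("orbit labels count invaders per block and canonicalize the swap", {
  expect_identical(unname(reduce_state(2, integer(0))), c(0L, 0L, 0L, 0L))
  expect_identical(unname(reduce_state(2, 0:5)), c(1L, 2L, 2L, 1L))
  # one A-clique vertex + extra vertex v: (k,e) = (1,0) >lex (0,1), no swap
  expect_identical(unname(reduce_state(2, c(0, 5))), c(0L, 1L, 0L, 1L))
  # mirror image {2, 4} (one B-vertex + u) canonicalizes to the same orbit
  expect_identical(reduce_state(2, c(2, 4)), reduce_state(2, c(0, 5)))
  expect_error(reduce_state(2, 6), "outside")
})

test_that("orbit labels are invariant under every generator of the symmetry", {
  set.seed(5)
  for (n in 2:3) {
    N <- 2L * n + 2L
    swap <- c(n:(2 * n - 1), 0:(n - 1), N - 1L, N - 2L) # (A,u)<->(B,v)
    for (rep in 1:20) {
      S <- which(runif(N) < 0.5) - 1L
      expect_identical(reduce_state(n, S), reduce_state(n, swap[S + 1L]))
      # permuting inside half A never changes the orbit
      permA <- sample(0:(n - 1))
      mapped <- ifelse(S < n, permA[S + 1L], S)
      expect_identical(reduce_state(n, S), reduce_state(n, mapped))
    }
  }
})

test_that("reduced state space has N(N+1)/2 canonical states", {
  expect_identical(nrow(reduced_state_space(2)), 21L)
  expect_identical(nrow(reduced_state_space(3)), 36L)
  expect_identical(nrow(reduced_state_space(4)), 55L)
  for (n in 2:11) {
    N <- 2L * n + 2L
    expect_identical(nrow(reduced_state_space(n)), as.integer(N * (N + 1) / 2))
  }
  # unbalanced spaces have no swap symmetry: 4 (p+1) (q+1) states
  expect_identical(nrow(reduced_state_space(NULL, p = 1, q = 3)), 4L * 2L * 4L)
  sp <- reduced_state_space(2)
  expect_identical(unlist(sp[1, ], use.names = FALSE), c(0L, 0L, 0L, 0L))
  expect_identical(unlist(sp[nrow(sp), ], use.names = FALSE), c(1L, 2L, 2L, 1L))
})

test_that("lumped transition rows are probability distributions", {
  for (n in 2:3) {
    sp <- reduced_state_space(n)
    for (i in seq_len(nrow(sp))) {
      row <- lumped_transition_row(n, unlist(sp[i, ]), r = "5/3")
      total <- Reduce(function(a, b) rat_arith(a, b, "+"), row$prob, "0")
      expect_rat_equal(total, "1")
    }
  }
  # absorbing orbits only loop on themselves
  expect_rat_equal(lumped_transition(2, c(0, 0, 0, 0), c(0, 0, 0, 0), 2), "1")
  expect_rat_equal(lumped_transition(2, c(1, 2, 2, 1), c(1, 2, 2, 1), 2), "1")
  expect_rat_equal(lumped_transition(2, c(0, 0, 0, 0), c(0, 1, 0, 0), 2), "0")
  expect_error(lumped_transition(2, c(1, 0, 1, 1), c(0, 0, 0, 0), 2), "not canonical")
})

test_that("lumped chain reproduces the full-state solve exactly", {
  # balanced case at an off-grid rational fitness
  expect_identical(reduced_fixation(2, "3/2"),
                   average_fixation(make_ell_graph(2), "3/2"))
  # unbalanced generalization (no swap symmetry) against the 2^6 solve
  for (r in c("1/2", "2")) {
    expect_identical(reduced_fixation(NULL, r, p = 1, q = 3),
                     average_fixation(make_unbalanced_ell(1, 3), r))
  }
})

test_that("the uniform average recombines the per-orbit values", {
  n <- 2
  res <- reduced_fixation(n, "2", per_orbit = TRUE)
  sp <- res$states
  find <- function(e, k, kp, ep) {
    which(sp$e == e & sp$k == k & sp$kp == kp & sp$ep == ep)
  }
  clique <- res$per_orbit[find(0, 1, 0, 0)]
  extra <- res$per_orbit[find(1, 0, 0, 0)]
  N <- 2 * n + 2
  manual <- rat_arith(
    rat_arith(rat_arith(clique, 2 * n, "*"), rat_arith(extra, 2, "*"), "+"),
    N, "/")
  expect_rat_equal(manual, res$average)
  expect_rat_equal(reduced_fixation(2, 1), "1/6")
})
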