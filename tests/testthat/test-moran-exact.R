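test_that("replacement weights and total weight follow the kernel definition", {
  expect_rat_equal(replacement_weight(make_complete(2), 0, 1), "1")
  expect_rat_equal(replacement_weight(make_star(3), 3, 0), "1/3")
  expect_rat_equal(replacement_weight(make_star(3), 0, 1), "0") # leaves not adjacent
  expect_error(replacement_weight(make_star(3), 0, 9), "invalid vertex")
  expect_rat_equal(total_weight(S = integer(0), r = "7/2", n_vertices = 5), "5")
  expect_rat_equal(total_weight(S = 0:4, r = 3, n_vertices = 5), "15")
  expect_rat_equal(total_weight(size = 2, r = 2, n_vertices = 6), "8")
})

test_that("one-step transition probabilities implement the four cases", {
  k2 <- make_complete(2)
  expect_rat_equal(transition_probability(k2, 0, c(0, 1), 2), "2/3") # gain: r/(r+1)
  expect_rat_equal(transition_probability(k2, 0, integer(0), 2), "1/3") # loss
  # |S delta S2| >= 2 is impossible in one step
  g <- make_complete(4)
  expect_rat_equal(transition_probability(g, 0, c(1, 2), "5/2"), "0")
  expect_rat_equal(transition_probability(g, c(0, 1), c(2, 3), 2), "0")
})

test_that("transition kernel rows sum to one exactly", {
  set.seed(11)
  graphs <- list(make_star(3), make_ell_graph(2), make_cycle(5))
  for (g in graphs) {
    N <- g$n_vertices
    for (r in c("1/2", "1", "3", "22/7")) {
      for (rep in 1:3) {
        S <- which(runif(N) < 0.5) - 1L
        total <- "0"
        # all possibly-reachable targets: self plus Hamming-1 neighbors
        targets <- c(list(S), lapply(0:(N - 1), function(v) {
          if (v %in% S) setdiff(S, v) else c(S, v)
        }))
        for (T in targets) {
          total <- rat_arith(total, transition_probability(g, S, T, r), "+")
        }
        expect_rat_equal(total, "1")
      }
    }
  }
})

test_that("full-state solve matches hand solutions and closed forms", {
  # K2 at r = 2: the 4-state chain solves to r/(r+1) = 2/3
  f <- fixation_vector(make_complete(2), 2, per_state = TRUE)
  expect_identical(f$per_vertex, c("2/3", "2/3"))
  expect_identical(f$per_state, c("0", "2/3", "2/3", "1"))
  # neutral drift: average fixation is 1/N on any connected graph
  for (g in list(make_star(4), make_ell_graph(2), make_complete_bipartite(2, 3))) {
    expect_rat_equal(average_fixation(g, 1), paste0("1/", g$n_vertices))
  }
})

test_that("isothermal graphs reproduce the well-mixed formula exactly", {
  cases <- list(make_complete(6), make_cycle(5), make_complete_bipartite(3, 3))
  for (g in cases) {
    for (r in c("1/2", "2", "7/3")) {
      expect_identical(average_fixation(g, r), phi0_exact(r, g$n_vertices))
    }
  }
  # and the ell-graph of order 6 is strictly below the baseline at r = 2
  expect_lt(rat_cmp(average_fixation(make_ell_graph(2), 2), phi0_exact(2, 6)), 0)
})

test_that("exact solver agrees with the numeric kernel oracle", {
  set.seed(23)
  graphs <- list(make_star(4), make_unbalanced_ell(1, 2), make_cycle(5))
  for (g in graphs) {
    for (r in c("3/4", "2")) {
      exact <- rat_num(average_fixation(g, r))
      expect_equal(exact, numeric_fixation_oracle(g, r), tolerance = 1e-10)
    }
  }
})

test_that("fixation probabilities are monotone in state and in fitness", {
  g <- make_ell_graph(2)
  f <- fixation_vector(g, "3/2", per_state = TRUE)
  N <- g$n_vertices
  phis <- f$per_state
  for (s in 0:(2^N - 1)) {
    for (v in 0:(N - 1)) {
      if (bitwAnd(s, bitwShiftL(1L, v)) == 0) {
        larger <- bitwOr(s, bitwShiftL(1L, v))
        expect_lte(rat_cmp(phis[s + 1], phis[larger + 1]), 0)
      }
    }
  }
  rs <- c("1/2", "1", "3/2", "2", "4")
  avgs <- vapply(rs, function(r) average_fixation(g, r), "")
  for (i in seq_len(length(rs) - 1)) {
    expect_lt(rat_cmp(avgs[i], avgs[i + 1]), 0)
  }
})

test_that("solver refuses ill-posed inputs", {
  disc <- moran_graph(rbind(c(0, 1), c(2, 3)), 4)
  expect_error(fixation_vector(disc, 2), "components: \\{0,1\\} \\{2,3\\}")
  expect_error(fixation_vector(make_complete(2), 0), "positive")
  expect_error(fixation_vector(make_complete(2), "-1"), "positive")
  big <- make_cycle(15)
  expect_error(fixation_vector(big, 2), "refused")
})
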