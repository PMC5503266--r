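test_that("wilson intervals bracket the point estimate inside [0, 1]", {
  ci <- wilson_interval(0, 100)
  expect_identical(unname(ci["lower"]), 0)
  expect_gt(ci["upper"], 0)
  ci <- wilson_interval(95, 100, level = 0.99)
  expect_true(ci["lower"] <= 0.95 && 0.95 <= ci["upper"])
  expect_true(all(ci >= 0 & ci <= 1))
  expect_error(wilson_interval(5, 4), "fixations")
})

test_that("estimates are bit-reproducible under a seed", {
  g <- make_ell_graph(2)
  a <- estimate_fixation(g, 2, 5000, seed = 99)
  b <- estimate_fixation(g, 2, 5000, seed = 99)
  expect_identical(unclass(a), unclass(b))
  c <- estimate_fixation(g, 2, 5000, seed = 100)
  expect_false(identical(a$fixations, c$fixations))
})

test_that("single trials absorb and extreme fitness behaves as expected", {
  g <- make_complete(2)
  est <- estimate_fixation(g, 2, trials = 1, seed = 1)
  expect_true(est$p_hat %in% c(0, 1))
  # overwhelming fitness: fixation almost every trial
  est <- estimate_fixation(g, 1e6, trials = 200, seed = 2)
  expect_gt(est$p_hat, 0.98)
  # r = 0: the invader cannot reproduce, extinction is certain
  est <- estimate_fixation(make_star(3), 0, trials = 200, seed = 3)
  expect_identical(est$fixations, 0L)
})

test_that("embedded-chain estimates agree with exact values", {
  # K6 against the closed form
  est <- estimate_fixation(make_complete(6), 2, trials = 1e5, seed = 42)
  p <- rat_num(phi0_exact(2, 6))
  se <- sqrt(p * (1 - p) / est$trials)
  expect_lt(abs(est$p_hat - p), 4 * se)
  # ell-graph of order 6 against the lumped solve
  est <- estimate_fixation(make_ell_graph(2), 2, trials = 1e5, seed = 43)
  p <- rat_num(reduced_fixation(2, 2))
  se <- sqrt(p * (1 - p) / est$trials)
  expect_lt(abs(est$p_hat - p), 4 * se)
  expect_true(est$ci_low <= p && p <= est$ci_high)
})

test_that("start vertex is irrelevant on a vertex-transitive graph", {
  g <- make_complete(6)
  p <- rat_num(phi0_exact(2, 6))
  set.seed(7)
  for (v in c(0, 3, 5)) {
    est <- estimate_fixation(g, 2, trials = 2e4, start = v)
    se <- sqrt(p * (1 - p) / est$trials)
    expect_lt(abs(est$p_hat - p), 5 * se)
  }
})

test_that("delta curves carry exact baselines and handle r = 0", {
  g <- make_complete(4)
  tab <- delta_curve(g, c(0, 1, 2), trials = 2e4, seed = 5)
  expect_identical(names(tab), c("r", "trials", "fixations", "p_hat",
                                 "ci_low", "ci_high", "phi0", "delta_hat"))
  expect_identical(tab$fixations[tab$r == 0], 0L)
  expect_equal(tab$phi0[tab$r == 2], 8 / 15)
  # complete graph: estimated deviation should be within the CI of zero
  covered <- abs(tab$delta_hat) <= (tab$ci_high - tab$ci_low) / 2 + 1e-12
  expect_true(all(covered[tab$r > 0]))
})
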