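test_that("well-mixed closed forms evaluate correctly", {
  expect_rat_equal(phi0_exact(1, 10), "1/10")
  expect_rat_equal(phi0_exact(2, 3), "4/7")
  expect_equal(phi0(2, 3), 4 / 7)
  expect_equal(phi0(c(1, 2), 6), c(1 / 6, 32 / 63))
  # phi0 increases to 1 with r
  expect_gt(phi0(100, 5), 0.99)
  expect_rat_equal(phi2_exact(1, 7), "1/7")
  expect_rat_equal(phi2_exact(2, 2), phi0_exact(4, 2)) # = 4/5
  for (r in c(1.5, 2, 5)) expect_gt(phi2(r, 6), phi0(r, 6))
})

test_that("degree bound and interpolation nodes match the reduction", {
  expect_identical(degree_bound(6), 19L)
  expect_identical(degree_bound(8), 34L)
  expect_identical(degree_bound(10), 53L)
  expect_error(degree_bound(7), "even")
  expect_identical(evaluation_points(2), c("1", "2", "3", "1/2"))
  pts <- evaluation_points(19)
  expect_length(pts, 38L)
  expect_false(anyDuplicated(pts) > 0)
  expect_true(all(rat_num(pts) > 0))
})

test_that("reconstruction round-trips planted rational functions", {
  pts <- c(evaluation_points(4), "17/5")
  f0 <- rational_function(c(1, 0, 1), c(1, 1, 1)) # (r^2+1)/(r^2+r+1)
  f <- reconstruct_rational(pts, rf_eval(f0, pts), d = 2)
  expect_identical(f$num, c("1", "0", "1"))
  expect_identical(f$den, c("1", "1", "1"))
  expect_identical(attr(f, "degree_used"), 2L)
  # requested degree above the true one: rank defect drops it automatically
  f2 <- reconstruct_rational(pts, rf_eval(f0, pts), d = 4)
  expect_identical(attr(f2, "degree_used"), 2L)
  expect_identical(rf_eval(f2, "9/4"), rf_eval(f0, "9/4"))
})

test_that("reconstruction certification rejects inconsistent data", {
  pts <- c(evaluation_points(3), "8", "9")
  f0 <- rational_function(c(2, 1, 0, 1), c(3, 0, 2, 1))
  vals <- rf_eval(f0, pts)
  vals[length(vals)] <- rat_arith(vals[length(vals)], "1/1000", "+")
  expect_error(reconstruct_rational(pts, vals, d = 3), "certification failure")
})

test_that("sign certification isolates roots exactly", {
  expect_identical(certify_sign(c(-1, 1), 1, Inf), "always+") # r - 1
  expect_identical(certify_sign(c(-15, 8, -1), 1, Inf), "mixed") # -(r-3)(r-5)
  expect_identical(certify_sign(c(1, 0, 1), 1, Inf), "always+") # r^2 + 1
  expect_identical(certify_sign(c(0, 0), 0, 1), "zero")
  # root at the endpoint is excluded; interval parity handled
  expect_identical(certify_sign(c(-1, 1), 0, 1), "always-") # r - 1 < 0 on (0,1)
  expect_identical(certify_sign(c(1, -2, 1), 1, Inf), "always+") # (r-1)^2
  expect_identical(certify_sign(c(1, -2, 1), 0, 1), "always+")
  # clustered roots inside the interval
  p <- c(6, -11, 6, -1) # -(r-1)(r-2)(r-3)
  expect_identical(certify_sign(p, 1, Inf), "mixed")
  expect_identical(certify_sign(p, 3, Inf), "always-")
  expect_identical(certify_sign(p, "5/2", 3), "always+")
})

test_that("delta of the well-mixed function itself vanishes identically", {
  N <- 5L
  # phi0 as a rational function: (r^N - r^{N-1}) / (r^N - 1)
  num <- c(rep(0, N - 1), -1, 1)
  den <- c(-1, rep(0, N - 1), 1)
  f <- rational_function(num, den)
  dl <- delta_function(f, N)
  expect_true(all(dl$num == "0"))
  v <- classify(f, n_vertices = N)
  expect_identical(v$label, "isothermal-neutral")
})

test_that("the order-6 ell-graph certifies as a suppressor symbolically", {
  f <- reconstruct_ell_phi(2)
  expect_identical(attr(f, "n_vertices"), 6L)
  expect_rat_equal(rf_eval(f, 1), "1/6")
  # held-out node never used anywhere in the pipeline
  expect_identical(rf_eval(f, "7/3"), reduced_fixation(2, "7/3"))
  v <- classify(f)
  expect_identical(v$label, "suppressor")
  expect_identical(v$sign_above_1, "always-")
  expect_identical(v$sign_below_1, "always+")
  # delta at sample points: negative above 1, zero at 1, positive below
  dl <- delta_function(f)
  expect_lt(rat_num(rf_eval(dl, 2)), 0)
  expect_rat_equal(rf_eval(dl, 1), "0")
  expect_gt(rat_num(rf_eval(dl, "1/2")), 0)
})

test_that("grid classification labels the reference families", {
  grid <- seq(0.5, 4, by = 0.5)
  expect_identical(classify(make_complete(4), r_grid = grid)$label, "isothermal-neutral")
  expect_identical(classify(make_star(5), r_grid = grid)$label, "amplifier")
  expect_identical(classify(make_ell_graph(2), r_grid = grid)$label, "suppressor")
  v <- classify(make_complete_bipartite(2, 3), r_grid = grid)
  expect_true(v$label %in% c("amplifier", "mixed"))
  expect_identical(nrow(v$evidence), length(grid))
})
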