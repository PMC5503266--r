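test_that("complete graphs have all pairs adjacent and are isothermal", {
  g2 <- make_complete(2)
  expect_identical(g2$edges, matrix(c(0L, 1L), 1))
  expect_identical(g2$degree, c(1L, 1L))
  g6 <- make_complete(6)
  expect_identical(nrow(g6$edges), 15L)
  expect_true(all(g6$degree == 5L))
  expect_true(is_isothermal(make_complete(4)))
  expect_error(make_complete(1), "invalid order")
})

test_that("star graphs have the right degree sequence and temperatures", {
  g <- make_star(5)
  expect_identical(g$n_vertices, 6L)
  expect_identical(sort(g$degree, decreasing = TRUE), c(5L, 1L, 1L, 1L, 1L, 1L))
  # m = 1 star is the single edge
  expect_identical(canonical_form(make_star(1)), canonical_form(make_complete(2)))
  # center temperature m, leaf temperature 1/m
  expect_rat_equal(vertex_temperature(make_star(3), 3), "3")
  expect_rat_equal(vertex_temperature(make_star(3), 0), "1/3")
  expect_error(make_star(0), "invalid order")
})

test_that("complete bipartite graphs generalize stars and cycles", {
  expect_identical(canonical_form(make_complete_bipartite(1, 4)),
                   canonical_form(make_star(4)))
  g22 <- make_complete_bipartite(2, 2) # the 4-cycle
  expect_true(is_isothermal(g22))
  expect_identical(canonical_form(g22), canonical_form(make_cycle(4)))
  expect_identical(sort(make_complete_bipartite(2, 3)$degree, decreasing = TRUE),
                   c(3L, 3L, 2L, 2L, 2L))
})

test_that("ell-graphs follow the fixed labeling and edge count", {
  for (n in 2:5) {
    g <- make_ell_graph(n)
    expect_identical(g$n_vertices, 2L * n + 2L)
    # clique vertices 0..2n-1 have degree 2n; extras have degree n+1
    expect_identical(g$degree, c(rep(2L * n, 2L * n), rep(n + 1L, 2)))
    expect_identical(nrow(g$edges), as.integer(choose(2L * n, 2) + 2L * n + 1L))
    expect_true(is_connected(g))
    # construction matches the by-hand definition edge for edge
    expect_identical(g$edges, moran_graph(ell_edges_by_hand(n, n))$edges)
  }
  expect_error(make_ell_graph(1), "invalid order")
})

test_that("swapping the halves together with the extras is an automorphism", {
  for (n in 2:4) {
    g <- make_ell_graph(n)
    N <- 2L * n + 2L
    # sigma: A <-> B, u <-> v
    sigma <- c((n:(2 * n - 1)), (0:(n - 1)), N - 1L, N - 2L)
    mapped <- moran_graph(matrix(sigma[g$edges + 1L], ncol = 2), N)
    expect_identical(mapped$edges, g$edges)
  }
})

test_that("unbalanced ell-graphs: degrees, consistency check, balanced case", {
  g13 <- make_unbalanced_ell(1, 3) # order 6
  expect_identical(g13$n_vertices, 6L)
  expect_identical(g13$degree[5:6], c(2L, 4L)) # u sees 1 clique vertex + v; v sees 3 + u
  g23 <- make_unbalanced_ell(2, 3, total_order = 7)
  expect_identical(g23$n_vertices, 7L)
  expect_error(make_unbalanced_ell(2, 3, total_order = 6), "inconsistent")
  expect_identical(canonical_form(make_unbalanced_ell(2, 2)),
                   canonical_form(make_ell_graph(2)))
})

test_that("vertex temperatures are exact and flag isothermal graphs", {
  expect_true(all(vertex_temperature(make_complete(7)) == "1"))
  expect_rat_equal(vertex_temperature(make_ell_graph(2), 4), "5/6") # u: 1/4+1/4+1/3
  expect_false(is_isothermal(make_ell_graph(2)))
  expect_true(is_isothermal(make_cycle(5)))
  expect_error(vertex_temperature(make_complete(3), 3), "invalid vertex")
})

test_that("graph validation rejects malformed structures", {
  expect_error(moran_graph(rbind(c(1, 1))), "self-loop")
  expect_error(moran_graph(rbind(c(0, 1), c(1, 0))), "duplicate")
  expect_error(moran_graph(rbind(c(0, 1)), n_vertices = 3), "isolated")
  expect_error(moran_graph(rbind(c(0, 2)), n_vertices = 2), "exceeds")
})

test_that("edge-list files round-trip and tolerate comments", {
  g <- make_ell_graph(2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edgelist(g, path)
  expect_identical(read_edgelist(path)$edges, g$edges)
  writeLines(c("# a triangle", "0 1", "", "1 2", "0 2"), path)
  expect_identical(canonical_form(read_edgelist(path)),
                   canonical_form(make_complete(3)))
  writeLines(c("0 1 2"), path)
  expect_error(read_edgelist(path), "malformed")
  # shipped example file is the order-6 ell-graph
  shipped <- system.file("extdata", "ell6.txt", package = "moranfix")
  expect_identical(read_edgelist(shipped)$edges, g$edges)
})

test_that("enumeration produces one representative per isomorphism class", {
  counts <- vapply(2:6, function(N) length(enumerate_connected_graphs(N)), 0L)
  expect_identical(counts, c(1L, 2L, 6L, 21L, 112L))
  expect_error(enumerate_connected_graphs(8), "refused")
  # N = 6 list contains the ell-graph of order 6
  keys <- vapply(enumerate_connected_graphs(6), canonical_form, "")
  expect_true(canonical_form(make_ell_graph(2)) %in% keys)
  expect_false(anyDuplicated(keys) > 0)
})

test_that("refined canonical form agrees with the N!-permutation oracle", {
  for (N in 3:5) {
    oracle_keys <- bruteforce_connected_classes(N)
    got <- enumerate_connected_graphs(N)
    expect_identical(sort(vapply(got, canonical_form, "", full = TRUE)), oracle_keys)
  }
  # spot check: refined key separates non-isomorphic graphs igraph separates
  g1 <- make_star(3); g2 <- make_cycle(4)
  expect_false(canonical_form(g1) == canonical_form(g2))
  expect_false(igraph::isomorphic(as_igraph(g1), as_igraph(g2)))
})
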