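#' Replacement weight w_ij
#'
#' The birth-death kernel places offspring of `i` on a uniformly chosen
#' neighbor: `w_ij = 1/d_i` when `i ~ j`, else 0.
#'
#' @param g a [moran_graph()].
#' @param i,j 0-based vertex ids.
#' @return canonical rational string.
#' @export
replacement_weight <- function(g, i, j) {
  stopifnot_graph(g)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 0 || j < 0 || i >= g$n_vertices || j >= g$n_vertices)
    stop("invalid vertex id")
  adjacent <- any(g$edges[, 1] == min(i, j) & g$edges[, 2] == max(i, j))
  if (adjacent) as_rational(paste0("1/", g$degree[i + 1L])) else "0"
}

#' Total reproductive weight of a population state
#'
#' With `|S|` invaders of fitness `r` among `N` individuals the total
#' reproductive weight is *r*|S| + (N - |S|); it is the normalizer of the
#' one-step kernel.
#'
#' @param S invader vertex set (0-based ids), or its size as a single
#'   integer via `size`.
#' @param r fitness (any form accepted by [as_rational()]).
#' @param n_vertices population size N.
#' @param size optional `|S|` given directly instead of `S`.
#' @return canonical rational string.
#' @export
total_weight <- function(S = NULL, r, n_vertices, size = NULL) {
  if (is.null(size)) {
    size <- length(unique(as.integer(S)))
  }
  size <- as.integer(size)
  n_vertices <- as.integer(n_vertices)
  if (size < 0 || size > n_vertices) stop("invalid invader count")
  rat_arith(rat_arith(as_rational(r), size, "*"), n_vertices - size, "+")
}

#' One-step transition probability of the Moran chain
#'
#' Exact probability of moving from invader set `S` to `S2` in one step:
#' nonzero only when `S2` gains exactly one vertex (invasion), loses exactly
#' one (recovery), or equals `S` (self-loop, the lazy mass).
#'
#' @param g a [moran_graph()].
#' @param S,S2 invader vertex sets, 0-based ids (may be empty: `integer(0)`).
#' @param r fitness.
#' @return canonical rational string.
#' @export
transition_probability <- function(g, S, S2, r) {
  stopifnot_graph(g)
  cpp_transition_probability(g$edges, g$n_vertices,
                             as.integer(unique(S)), as.integer(unique(S2)),
                             as_rational(r))
}

#' Exact fixation probabilities by full-state solve
#'
#' Solves the absorbing Markov chain on all `2^N` invader sets exactly over
#' arbitrary-precision rationals.  The chain only moves between adjacent
#' invader-count levels, so the transient system is block tridiagonal in
#' level order and is eliminated level by level (the self-loop mass never
#' enters; the embedded chain has the same absorption probabilities).
#' Requires a connected graph — otherwise fixation is not reachable from
#' every state and the boundary-value problem is ill-posed.
#'
#' @param g a connected [moran_graph()] with at most `max_order` vertices.
#' @param r fitness, positive.
#' @param per_state also return the fixation probability of every subset,
#'   indexed by bitmask (bit `i` = vertex `i`); allowed for `N <= 12`.
#' @param max_order refusal threshold for the full-state mode (default 14);
#'   beyond it use [reduced_fixation()] or [estimate_fixation()].
#' @return object of class `moran_fixation`: list with `per_vertex`
#'   (rational strings, singleton starts), `average` (uniform-start mean),
#'   `r`, `n_vertices`, and optionally `per_state`.
#' @examples
#' f <- fixation_vector(make_complete(2), 2)
#' f$per_vertex   # "2/3" "2/3": r/(r+1)
#' @export
fixation_vector <- function(g, r, per_state = FALSE, max_order = 14) {
  stopifnot_graph(g)
  if (g$n_vertices > max_order) {
    stop(sprintf(
      "full-state solve refused for N = %d > %d; use reduced_fixation() or estimate_fixation()",
      g$n_vertices, max_order))
  }
  if (per_state && g$n_vertices > 12) stop("per_state output limited to N <= 12")
  connected_or_stop(g)
  r <- as_rational(r)
  if (rat_cmp(r, 0L) <= 0) stop("fitness r must be positive")
  res <- cpp_fixation_full(g$edges, g$n_vertices, r, per_state)
  structure(list(per_vertex = res$per_vertex,
                 average = res$average,
                 per_state = res$per_state,
                 r = r, n_vertices = g$n_vertices),
            class = "moran_fixation")
}

#' @export
print.moran_fixation <- function(x, ...) {
  cat(sprintf("Moran fixation probabilities (N = %d, r = %s)\n", x$n_vertices, x$r))
  cat(sprintf("  average: %s ~ %.6f\n", x$average, rat_num(x$average)))
  pv <- rat_num(x$per_vertex)
  cat(sprintf("  per-vertex range: [%.6f, %.6f]\n", min(pv), max(pv)))
  invisible(x)
}

#' Average fixation probability
#'
#' Mean of the single-invader fixation probabilities over a uniformly random
#' start vertex, computed exactly via [fixation_vector()].
#'
#' @inheritParams fixation_vector
#' @return canonical rational string.
#' @examples
#' average_fixation(make_complete(6), 2)  # "32/63", the well-mixed value
#' @export
average_fixation <- function(g, r, max_order = 14) {
  fixation_vector(g, r, per_state = FALSE, max_order = max_order)$average
}
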