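#' Well-mixed fixation probability
#'
#' For a single invader of fitness `r` in an unstructured population of size
#' `N`, `phi0(r) = r^(N-1) (r - 1) / (r^N - 1)`, extended by continuity to
#' `1/N` at r = 1.  `phi0()` works in doubles; `phi0_exact()` over exact
#' rationals.  `phi2()` is the reference upper envelope for star-like
#' amplifiers: `phi0` evaluated at `r^2`.
#'
#' @param r fitness, positive; vectorized for the numeric versions.
#' @param n_vertices population size N, at least 2.
#' @return `phi0()`, `phi2()`: double; `phi0_exact()`, `phi2_exact()`:
#'   canonical rational string.
#' @examples
#' phi0(2, 3)           # 4/7
#' phi0_exact("1", 10)  # "1/10"
#' @export
phi0 <- function(r, n_vertices) {
  stopifnot(all(r > 0), n_vertices >= 2)
  ifelse(r == 1, 1 / n_vertices,
         r^(n_vertices - 1) * (r - 1) / (r^n_vertices - 1))
}

#' @rdname phi0
#' @export
phi0_exact <- function(r, n_vertices) {
  vapply(as_rational(r), cpp_phi0, "", N = as.integer(n_vertices), USE.NAMES = FALSE)
}

#' @rdname phi0
#' @export
phi2 <- function(r, n_vertices) phi0(r^2, n_vertices)

#' @rdname phi0
#' @export
phi2_exact <- function(r, n_vertices) {
  vapply(as_rational(r), cpp_phi2, "", N = as.integer(n_vertices), USE.NAMES = FALSE)
}

#' Degree bound for the ell-graph fixation function
#'
#' The fixation probability of any order-N graph is a quotient of
#' polynomials in `r` of degree at most `2^N - 2`.  For ell-graphs the
#' symmetry reduction lowers the bound to `d = N(N+1)/2 - 2` — 19, 34, 53
#' for orders 6, 8, 10 — which sets the size of the interpolation problem.
#'
#' @param n_vertices even order `N = 2n + 2 >= 6` of the ell-graph.
#' @return integer degree bound.
#' @export
degree_bound <- function(n_vertices) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 6 || n_vertices %% 2 != 0)
    stop("degree bound applies to ell-graph orders: even N >= 6")
  (n_vertices * (n_vertices + 1L)) %/% 2L - 2L
}

#' Interpolation nodes for rational-function reconstruction
#'
#' The `2d` fitness values at which the exact fixation probability is
#' evaluated to set up the linear system: the integers `1..d+1` and the
#' reciprocals `1/2..1/d` — the lowest-complexity rationals, chosen to keep
#' the bit-size of the exact solution under control.
#'
#' @param d degree bound, at least 2.
#' @return character vector of `2d` distinct rational strings.
#' @examples
#' evaluation_points(2)  # "1" "2" "3" "1/2"
#' @export
evaluation_points <- function(d) {
  d <- as.integer(d)
  if (is.na(d) || d < 2) stop("need d >= 2")
  c(as.character(1:(d + 1)), paste0("1/", seq_len(d)[-1]))
}

#' Rational function with exact coefficients
#'
#' Quotient of two polynomials in the fitness `r` with exact rational
#' coefficients, stored ascending (`num[i]` multiplies `r^(i-1)`).
#'
#' @param num,den coefficient vectors in any form accepted by
#'   [as_rational()].
#' @return object of class `rational_fn`.
#' @export
rational_function <- function(num, den) {
  num <- as_rational(num); den <- as_rational(den)
  if (all(den == "0")) stop("zero denominator polynomial")
  structure(list(num = num, den = den), class = "rational_fn")
}

#' @export
print.rational_fn <- function(x, ...) {
  dn <- max(which(x$num != "0"), 1L) - 1L
  dd <- max(which(x$den != "0"), 1L) - 1L
  cat(sprintf("rational function: degree %d / degree %d\n", dn, dd))
  show_poly <- function(cf) {
    idx <- which(cf != "0")
    if (length(idx) == 0) return("0")
    terms <- sprintf("(%s) r^%d", cf[idx], idx - 1L)
    paste(terms, collapse = " + ")
  }
  if (length(x$num) <= 8) {
    cat("  num:", show_poly(x$num), "\n  den:", show_poly(x$den), "\n")
  } else {
    cat("  (coefficients suppressed; use $num / $den)\n")
  }
  invisible(x)
}

#' Evaluate a rational function exactly
#'
#' @param f a [rational_function()].
#' @param r evaluation point(s).
#' @return canonical rational string(s).
#' @export
rf_eval <- function(f, r) {
  stopifnot(inherits(f, "rational_fn"))
  vapply(as_rational(r), function(x) cpp_rf_eval(f$num, f$den, x), "",
         USE.NAMES = FALSE)
}

#' Reconstruct a rational function from exact evaluations
#'
#' Given exact pairs `(r, Phi(r))` and a degree bound `d`, solves the linear
#' system in the `2d` unknown coefficients of
#' `Phi = (a_0 + ... + a_{d-1} r^{d-1} + r^d) / (b_0 + ... + b_{d-1} r^{d-1} + r^d)`
#' (leading coefficients 1, as Phi tends to 1 when r tends to infinity).  If the system
#' is singular the true degree is lower: the rank defect equals the degree
#' excess, and the solve is retried once at the reduced degree.  Any
#' evaluation pairs beyond the `2d` used in the system serve as held-out
#' validation; a mismatch there is a hard error, so a returned function is
#' certified to reproduce every supplied pair exactly.
#'
#' @param r_values,phi_values exact evaluation pairs (forms accepted by
#'   [as_rational()]); at least `2d`, and at least 3 more than needed is
#'   recommended for held-out validation.
#' @param d degree bound (e.g. [degree_bound()]).
#' @return a [rational_function()] with attribute `"degree_used"`.
#' @examples
#' # round-trip a planted quotient (r^2 + 1) / (r^2 + r + 1)
#' pts <- c("1", "2", "3", "1/2", "4", "5", "6")
#' f0 <- rational_function(c(1, 0, 1), c(1, 1, 1))
#' f <- reconstruct_rational(pts, rf_eval(f0, pts), d = 2)
#' f$num   # "1" "0" "1"
#' @export
reconstruct_rational <- function(r_values, phi_values, d) {
  r_values <- as_rational(r_values)
  phi_values <- as_rational(phi_values)
  if (length(r_values) != length(phi_values)) stop("evaluation pairs must align")
  if (anyDuplicated(r_values)) stop("evaluation points must be distinct")
  d <- as.integer(d)
  if (is.na(d) || d < 1) stop("need d >= 1")
  if (length(r_values) < 2 * d) {
    stop(sprintf("need at least %d evaluation pairs for degree %d", 2 * d, d))
  }
  res <- cpp_reconstruct(r_values[1:(2 * d)], phi_values[1:(2 * d)], d)
  if (!res$ok) {
    d2 <- d - res$defect
    if (d2 < 1 || res$defect <= 0) stop("degenerate interpolation system")
    res <- cpp_reconstruct(r_values[1:(2 * d2)], phi_values[1:(2 * d2)], d2)
    if (!res$ok) stop("interpolation system still singular at reduced degree ", d2)
    d <- d2
  }
  f <- rational_function(res$num, res$den)
  # certify: every supplied pair must be reproduced exactly (the pairs not
  # used in the linear system act as held-out validation)
  got <- rf_eval(f, r_values)
  if (!identical(got, phi_values)) {
    bad <- r_values[got != phi_values]
    stop("certification failure: reconstruction mismatches held-out evaluation at r = ",
         paste(bad, collapse = ", "))
  }
  attr(f, "degree_used") <- d
  f
}

#' Exact fixation probability of an ell-graph as a function of fitness
#'
#' Full pipeline for the balanced ell-graph of order `N = 2n + 2`: evaluate
#' the lumped chain at the `2d` nodes of [evaluation_points()] with
#' `d = N(N+1)/2 - 2`, plus `n_holdout` extra nodes (`d+2, d+3, ...`), and
#' reconstruct the rational function `Phi(r)` by [reconstruct_rational()].
#' The held-out nodes certify the result.
#'
#' @inheritParams reduce_state
#' @param n_holdout extra validation nodes beyond the `2d` used in the
#'   system (default 3).
#' @return a certified [rational_function()] with attributes `"n_vertices"`
#'   and `"degree_used"`.
#' @export
reconstruct_ell_phi <- function(n, n_holdout = 3) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid order: need n >= 2")
  N <- 2L * n + 2L
  d <- degree_bound(N)
  pts <- c(evaluation_points(d), as.character(d + 1 + seq_len(n_holdout)))
  phis <- vapply(pts, function(r) reduced_fixation(n, r), "", USE.NAMES = FALSE)
  f <- reconstruct_rational(pts, phis, d)
  attr(f, "n_vertices") <- N
  f
}

#' Difference to the well-mixed baseline, as a reduced rational function
#'
#' `Delta(r) = Phi(r) - phi0(r)` over the common denominator
#' `(r^N - 1) * Phi''(r)`, reduced by the polynomial GCD (which removes the
#' removable singularity at r = 1 shared by numerator and denominator) and
#' normalized to primitive integer coefficients with a positive leading
#' denominator coefficient.
#'
#' @param f a [rational_function()] for `Phi`.
#' @param n_vertices population size N of the underlying graph.
#' @return a [rational_function()] for `Delta`.
#' @export
delta_function <- function(f, n_vertices = attr(f, "n_vertices")) {
  stopifnot(inherits(f, "rational_fn"))
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 2) stop("need the population size N")
  res <- cpp_delta_rf(f$num, f$den, n_vertices)
  rational_function(res$num, res$den)
}

#' Certify the sign of a polynomial on an interval
#'
#' Exact real-root isolation by Sturm sequences over the rationals: the
#' polynomial has constant (strict) sign on the open interval iff its
#' square-free part has no root there, and the sign is then read off one
#' rational sample point.  Roots exactly at the endpoints are divided out
#' first (they do not belong to the open interval).
#'
#' @param coefficients polynomial coefficients, ascending, in any form
#'   accepted by [as_rational()].
#' @param lower,upper interval endpoints; `upper` may be `Inf`.
#' @return one of `"always+"`, `"always-"`, `"mixed"`, `"zero"`.
#' @examples
#' certify_sign(c(1, 0, 1), 1, Inf)        # r^2 + 1: "always+"
#' certify_sign(c(-15, 8, -1), 1, Inf)     # -(r-3)(r-5): "mixed"
#' @export
certify_sign <- function(coefficients, lower, upper) {
  up <- if (is.numeric(upper) && is.infinite(upper)) "Inf" else as_rational(upper)
  cpp_certify_sign(as_rational(coefficients), as_rational(lower), up)
}

#' Classify a graph as suppressor or amplifier of selection
#'
#' A graph is an *amplifier of selection* when its average fixation
#' probability exceeds the well-mixed baseline for every fitness r > 1
#' (with the inequality reversed for r < 1), and a *suppressor* when it
#' falls below the baseline for every r > 1.  Two certification modes:
#'
#' * **grid** (for a [moran_graph()]): compute `Delta(r) = Phi(r) - phi0(r)`
#'   exactly at every grid point and require a strict, consistent sign at
#'   all points r > 1 and the opposite at all points r < 1.  The default
#'   grid is `0.25, 0.5, ..., 10`.
#' * **symbolic** (for a [rational_function()], e.g. from
#'   [reconstruct_ell_phi()]): certify the sign of `Delta` on the whole open
#'   intervals `(1, Inf)` and `(0, 1)` by Sturm sequences.  The denominator
#'   is first certified positive on `(0, Inf)` so the sign of `Delta` is the
#'   sign of its numerator; the forced root of the numerator at r = 1
#'   (where Delta(1) = 0) is divided out before the open-interval
#'   analysis.
#'
#' @param x a [moran_graph()] (grid mode) or [rational_function()]
#'   (symbolic mode).
#' @param mode `"grid"` or `"symbolic"`; defaults by input class.
#' @param r_grid fitness grid for grid mode, coerced to exact rationals.
#' @param n_vertices population size (symbolic mode; defaults to the
#'   function's `"n_vertices"` attribute).
#' @param ... unused.
#' @return object of class `moran_verdict`: list with `label` (one of
#'   `"suppressor"`, `"amplifier"`, `"isothermal-neutral"`, `"mixed"`),
#'   `mode`, `certificate` (human-readable evidence), and in grid mode the
#'   `evidence` table of exact values.
#' @export
classify <- function(x, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.moran_graph <- function(x, mode = "grid", r_grid = seq(0.25, 10, by = 0.25),
                                 ...) {
  if (!identical(mode, "grid"))
    stop("symbolic mode needs a rational_fn; graphs are classified on a grid")
  rs <- as_rational(r_grid)
  N <- x$n_vertices
  signs <- integer(length(rs))
  phis <- character(length(rs))
  phi0s <- phi0_exact(rs, N)
  for (i in seq_along(rs)) {
    phis[i] <- average_fixation(x, rs[i])
    signs[i] <- cpp_rat_cmp(phis[i], phi0s[i])
  }
  above <- rat_num(rs) > 1
  below <- rat_num(rs) < 1
  label <- if (all(signs == 0)) "isothermal-neutral"
  else if (all(signs[above] < 0) && all(signs[below] > 0)) "suppressor"
  else if (all(signs[above] > 0) && all(signs[below] < 0)) "amplifier"
  else "mixed"
  ev <- data.frame(r = rat_num(rs), r_exact = rs, phi = phis, phi0 = phi0s,
                   delta_sign = signs, stringsAsFactors = FALSE)
  structure(list(
    label = label, mode = "grid",
    certificate = sprintf(
      "exact sign of Delta at %d grid points in [%s, %s]: %d negative, %d zero, %d positive",
      length(rs), rs[1], rs[length(rs)], sum(signs < 0), sum(signs == 0), sum(signs > 0)),
    evidence = ev), class = "moran_verdict")
}

#' @rdname classify
#' @export
classify.rational_fn <- function(x, mode = "symbolic",
                                 n_vertices = attr(x, "n_vertices"), ...) {
  if (!identical(mode, "symbolic"))
    stop("grid mode needs a moran_graph; rational functions are certified symbolically")
  N <- as.integer(n_vertices)
  if (is.na(N)) stop("need the population size N")
  dl <- delta_function(x, N)
  if (all(as_rational(dl$num) == "0")) {
    return(structure(list(
      label = "isothermal-neutral", mode = "symbolic",
      certificate = "Delta is identically zero",
      sign_above_1 = "zero", sign_below_1 = "zero"), class = "moran_verdict"))
  }
  s_den <- certify_sign(dl$den, 0, Inf)
  if (s_den != "always+")
    stop("denominator of Delta not certified positive on (0, Inf): ", s_den)
  defl <- cpp_deflate_root(dl$num, "1")
  s_hi <- certify_sign(defl$coef, 1, Inf)         # sign of Delta on (1, Inf)
  raw_lo <- certify_sign(defl$coef, 0, 1)
  # on (0, 1) the removed factor (r-1)^m is negative for odd m
  s_lo <- if (defl$multiplicity %% 2 == 1) {
    switch(raw_lo, "always+" = "always-", "always-" = "always+", raw_lo)
  } else raw_lo
  num_zero <- all(as_rational(dl$num) == "0")
  label <- if (num_zero) "isothermal-neutral"
  else if (s_hi == "always-" && s_lo == "always+") "suppressor"
  else if (s_hi == "always+" && s_lo == "always-") "amplifier"
  else "mixed"
  structure(list(
    label = label, mode = "symbolic",
    certificate = sprintf(
      "Sturm: Delta'' %s on (0,Inf); (r-1)^%d removed from Delta'; Delta %s on (1,Inf), %s on (0,1)",
      s_den, defl$multiplicity, s_hi, s_lo),
    sign_above_1 = s_hi, sign_below_1 = s_lo), class = "moran_verdict")
}

#' @export
print.moran_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s  [%s mode]\n", x$label, x$mode))
  cat(" ", x$certificate, "\n")
  invisible(x)
}
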