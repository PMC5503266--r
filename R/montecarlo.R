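#' Wilson score interval
#'
#' Confidence interval for a binomial proportion.  Chosen over the normal
#' approximation because fixation probabilities are routinely near 0 (and
#' coverage must hold there at the 99% level).
#'
#' @param fixations number of successes.
#' @param trials number of trials.
#' @param level confidence level (default 0.99).
#' @return named numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(fixations, trials, level = 0.99) {
  stopifnot(trials >= 1, fixations >= 0, fixations <= trials)
  z <- qnorm(1 - (1 - level) / 2)
  p <- fixations / trials
  den <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / den
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Simulate one invasion to absorption
#'
#' Runs the embedded (self-loop-skipping) birth-death chain from a single
#' invader until extinction or fixation.  Each sampled event is a
#' replacement across the invader/resident frontier, drawn with probability
#' proportional to r\*w_ij (invasion) or `w_ij` (recovery); conditioning
#' on state-changing events leaves absorption probabilities untouched while
#' skipping the lazy steps that dominate when the frontier is small.
#'
#' Uses R's RNG stream: call `set.seed()` (or pass `seed` to
#' [estimate_fixation()]) for reproducibility.
#'
#' @param g a connected [moran_graph()].
#' @param r fitness, nonnegative double (r = 0 means the invader never
#'   reproduces and extinction is certain).
#' @param start 0-based start vertex, or `NULL` for uniformly random.
#' @return `TRUE` iff the invader fixed.
#' @export
simulate_once <- function(g, r, start = NULL) {
  stopifnot_graph(g)
  connected_or_stop(g)
  start <- if (is.null(start)) -1L else as.integer(start)
  if (start >= g$n_vertices) stop("invalid start vertex")
  cpp_mc_trials(g$edges, g$n_vertices, as.double(r), 1L, start) == 1L
}

#' Monte Carlo estimate of the fixation probability
#'
#' Repeats [simulate_once()] with a uniformly random start vertex (the
#' uniform-initialization convention behind the average fixation
#' probability) and aggregates into a point estimate with a Wilson score
#' confidence interval.  Bit-reproducible for fixed
#' `(seed, trials, g, r)`.
#'
#' @inheritParams simulate_once
#' @param trials number of independent invasions, at least 1.
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @param level confidence level (default 0.99).
#' @param start fixed 0-based start vertex, or `NULL` (default) for uniform.
#' @return object of class `mc_estimate`: list with `trials`, `fixations`,
#'   `p_hat`, `ci_low`, `ci_high`, `level`, `seed`, `r`.
#' @examples
#' est <- estimate_fixation(make_complete(4), 2, trials = 1e4, seed = 1)
#' est$p_hat            # close to phi0(2, 4) = 8/15
#' @export
estimate_fixation <- function(g, r, trials, seed = NULL, level = 0.99,
                              start = NULL) {
  stopifnot_graph(g)
  connected_or_stop(g)
  trials <- as.integer(trials)
  stopifnot(trials >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  start <- if (is.null(start)) -1L else as.integer(start)
  fix <- cpp_mc_trials(g$edges, g$n_vertices, as.double(r), trials, start)
  ci <- wilson_interval(fix, trials, level)
  structure(list(trials = trials, fixations = fix, p_hat = fix / trials,
                 ci_low = unname(ci["lower"]), ci_high = unname(ci["upper"]),
                 level = level, seed = seed, r = as.double(r)),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC fixation estimate: %.6g  (%d/%d trials, %g%% CI [%.6g, %.6g])\n",
              x$p_hat, x$fixations, x$trials, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Estimated deviation from the well-mixed baseline along a fitness grid
#'
#' For each grid fitness, a Monte Carlo estimate of the average fixation
#' probability plus the exact baseline `phi0(r)` and the estimated
#' difference `delta_hat = p_hat - phi0(r)`.  r = 0 is allowed (certain
#' extinction).  The CSV-ready table reproduces the suppressor/amplifier
#' deviation curves at whatever trial count the variance budget allows.
#'
#' @inheritParams estimate_fixation
#' @param r_grid nonnegative fitness values.
#' @return data.frame with columns `r, trials, fixations, p_hat, ci_low,
#'   ci_high, phi0, delta_hat`.
#' @export
delta_curve <- function(g, r_grid, trials, seed = NULL, level = 0.99) {
  stopifnot_graph(g)
  if (any(r_grid < 0)) stop("fitness values must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(r_grid, function(r) {
    est <- estimate_fixation(g, r, trials, seed = NULL, level = level)
    p0 <- if (r > 0) phi0(r, g$n_vertices) else 0
    data.frame(r = r, trials = est$trials, fixations = est$fixations,
               p_hat = est$p_hat, ci_low = est$ci_low, ci_high = est$ci_high,
               phi0 = p0, delta_hat = est$p_hat - p0)
  })
  do.call(rbind, rows)
}
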