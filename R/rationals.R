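#' Exact rationals as canonical strings
#'
#' All exact quantities in moranfix cross the R boundary as canonical
#' rational strings `"p/q"` (reduced, positive denominator; integers print
#' without the `/q`).  `as_rational()` converts R values to this form:
#' character strings are parsed and canonicalized, integers pass through,
#' and doubles are converted *exactly* (every finite double is a dyadic
#' rational, so e.g. `0.25` becomes `"1/4"` with no rounding).
#'
#' @param x character (`"p/q"` or `"p"`), integer, or double; vectorized.
#' @return character vector of canonical rational strings.
#' @examples
#' as_rational("10/4")   # "5/2"
#' as_rational(0.25)     # "1/4"
#' as_rational(2L)       # "2"
#' @export
as_rational <- function(x) {
  if (is.character(x)) return(vapply(x, cpp_rat_canon, "", USE.NAMES = FALSE))
  if (is.numeric(x)) {
    return(vapply(as.double(x), cpp_rat_from_double, "", USE.NAMES = FALSE))
  }
  stop("cannot interpret as rational: ", class(x)[1])
}

#' Compare two exact rationals
#'
#' @param a,b rationals in any form accepted by [as_rational()].
#' @return -1, 0 or 1 as `a < b`, `a == b`, `a > b` (exact comparison).
#' @export
rat_cmp <- function(a, b) cpp_rat_cmp(as_rational(a), as_rational(b))

#' Exact rational arithmetic
#'
#' @param a,b rationals in any form accepted by [as_rational()].
#' @param op one of `"+"`, `"-"`, `"*"`, `"/"`.
#' @return canonical rational string.
#' @export
rat_arith <- function(a, b, op) cpp_rat_arith(as_rational(a), as_rational(b), op)

#' Convert an exact rational to double
#'
#' @param x rational in any form accepted by [as_rational()]; vectorized.
#' @return double vector (rounded to nearest representable value).
#' @export
rat_num <- function(x) vapply(as_rational(x), cpp_rat_to_double, 0, USE.NAMES = FALSE)
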