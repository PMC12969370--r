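#' @useDynLib csfgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_radsum <- function(ptr) structure(list(ptr = ptr), class = "radsum")

#' Exact signed square roots of rationals
#'
#' The expansion coefficients of a genealogical CSF are products of
#' Clebsch-Gordan-derived factors, each of the form \eqn{\pm\sqrt{p/q}} with
#' \eqn{p/q} a nonnegative rational.  Sums of products of two such radicals
#' (as they appear in the graph overlap sweep) are no longer single radicals,
#' so exact values are held as finite sums \eqn{\sum_s c_s \sqrt{s}} with
#' squarefree integer radicands \eqn{s} and rational coefficients
#' \eqn{c_s}, over arbitrary-precision integers.  The set is closed under
#' addition and multiplication, so every quantity the graph algorithm
#' produces is represented exactly.
#'
#' `radical(p, q, sign)` constructs \eqn{\mathrm{sign}\cdot\sqrt{p/q}};
#' `rational(num, den)` constructs an exact rational.  Both return objects of
#' class `"radsum"` supporting `+`, `-`, `*`, `==`, `!=`, `as.numeric()` and
#' `format()`/`print()`.
#'
#' @param p,q nonnegative integer numerator and positive integer denominator
#'   of the radicand.
#' @param sign +1, -1 or 0.
#' @param num,den integer numerator and positive integer denominator.
#' @return An object of class `"radsum"`.
#' @examples
#' radical(1, 2) * radical(1, 3)        # sqrt(1/6)
#' radical(1, 4, sign = -1) * rational(-1)  # +sqrt(1/4), i.e. 1/2
#' as.numeric(radical(1, 72))           # 0.1178511
#' @export
radical <- function(p, q = 1, sign = 1L) {
  stopifnot(length(p) == 1, length(q) == 1, length(sign) == 1)
  new_radsum(rx_radical(as.integer(sign), as.double(p), as.double(q)))
}

#' @rdname radical
#' @export
rational <- function(num, den = 1) {
  new_radsum(rx_rational(as.double(num), as.double(den)))
}

#' @rdname radical
#' @export
radsum_zero <- function() new_radsum(rx_zero())

is_radsum <- function(x) inherits(x, "radsum")

#' Coerce a number to an exact radical sum
#'
#' Integer-valued numerics are converted exactly; anything else is rejected
#' (there is no exact representation of an arbitrary double).
#'
#' @param x a `radsum` or an integer-valued numeric scalar.
#' @return A `radsum`.
#' @export
as_radsum <- function(x) {
  if (is_radsum(x)) return(x)
  if (is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x))
    return(rational(x))
  stop("cannot coerce to an exact radical sum: ", deparse(substitute(x)))
}

#' @export
Ops.radsum <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_radsum(rx_neg(e1$ptr)))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for radsum")
  }
  a <- as_radsum(e1)
  b <- as_radsum(e2)
  switch(.Generic,
    "+" = new_radsum(rx_add(a$ptr, b$ptr)),
    "-" = new_radsum(rx_sub(a$ptr, b$ptr)),
    "*" = new_radsum(rx_mul(a$ptr, b$ptr)),
    "==" = rx_equal(a$ptr, b$ptr),
    "!=" = !rx_equal(a$ptr, b$ptr),
    stop(.Generic, " not defined for radsum")
  )
}

#' @export
as.double.radsum <- function(x, ...) rx_double(x$ptr)

#' @export
format.radsum <- function(x, ...) rx_format(x$ptr)

#' @export
print.radsum <- function(x, ...) {
  cat("<radsum> ", rx_format(x$ptr), "  (", format(rx_double(x$ptr), digits = 15),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname radical
#' @param x,a,b `radsum` objects.
#' @export
radsum_is_zero <- function(x) rx_is_zero(x$ptr)

#' @rdname radical
#' @export
radsum_equal <- function(a, b) rx_equal(as_radsum(a)$ptr, as_radsum(b)$ptr)

#' @rdname radical
#' @export
radical_mul <- function(a, b) a * b

#' @rdname radical
#' @export
radsum_add <- function(a, b) a + b

#' @rdname radical
#' @export
radsum_mul <- function(a, b) a * b

#' @rdname radical
#' @export
to_float <- function(x) {
  if (is_radsum(x)) rx_double(x$ptr) else as.double(x)
}

#' Term-by-term view of an exact radical sum
#'
#' @param x a `radsum`.
#' @return A data frame with one row per term: the squarefree radicand and the
#'   exact coefficient (decimal strings `num`/`den`, plus float views).
#' @export
radsum_terms <- function(x) {
  stopifnot(is_radsum(x))
  as.data.frame(rx_terms(x$ptr), stringsAsFactors = FALSE)
}

# internal fused acc + a*b used by the sweep and the oracle
rs_addmul <- function(acc, a, b) new_radsum(rx_addmul(acc$ptr, a$ptr, b$ptr))
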