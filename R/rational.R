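# Exact rational arithmetic for stoichiometric coefficients.
# A rational is an integer pair (num, den) with den > 0 and gcd(|num|, den) = 1.
# Coefficients in reaction tables are small, so plain doubles hold the
# integer numerators/denominators exactly.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

#' Construct an exact rational number
#'
#' Rationals are stored as reduced integer pairs and used for all
#' stoichiometric coefficients, so that atom and charge balances are exact
#' with no floating-point error.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero).
#' @return An object of class `rational` with fields `num` and `den`
#'   (`den > 0`, fraction in lowest terms).
#' @examples
#' rational(6, -4)   # -3/2
#' @export
rational <- function(num, den = 1) {
  if (length(num) != 1L || length(den) != 1L || !is.finite(num) || !is.finite(den))
    stop("rational() takes finite scalars", call. = FALSE)
  if (num != round(num) || den != round(den))
    stop("rational() takes integer numerator and denominator", call. = FALSE)
  if (den == 0) stop("zero denominator", call. = FALSE)
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  structure(list(num = num, den = den), class = "rational")
}

#' Coerce to a rational
#'
#' Accepts a `rational`, an integer-valued number, or a string `"p/q"`.
#'
#' @param x value to coerce.
#' @return A `rational`.
#' @export
as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.character(x)) {
    parts <- strsplit(trimws(x), "/", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(rational(as.numeric(parts)))
    if (length(parts) == 2L) return(rational(as.numeric(parts[1]), as.numeric(parts[2])))
    stop("cannot parse rational: ", x, call. = FALSE)
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x))
    return(rational(x))
  stop("cannot coerce to rational: ", format(x), call. = FALSE)
}

rat_add <- function(a, b) rational(a$num * b$den + b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rational(a$num * b$num, a$den * b$den)
rat_scale_int <- function(a, k) rational(a$num * k, a$den)
rat_is_zero <- function(a) a$num == 0

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.rational <- function(x, ...) {
  if (x$den == 1) format(x$num, scientific = FALSE)
  else paste0(format(x$num, scientific = FALSE), "/", format(x$den, scientific = FALSE))
}

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den
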