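#' Exact rational numbers for exponent algebra
#'
#' Allometric exponents are simple fractions (1/3, -1/6, 5/3, ...). Deriving
#' them through floating point would blur exactness, so the theory engine
#' carries exponents as reduced integer fractions. This is deliberately a
#' minimal rational type, not a general CAS: the constraint system it serves
#' is one linear chain plus a single unknown.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero).
#' @return An object of class `"rational"` with integer fields `num`, `den`,
#'   always in lowest terms with a positive denominator.
#' @examples
#' rational(2, 6)                       # 1/3
#' rational(1, 3) + rational(2, 3)      # 1
#' rational(1, 3) * 2L                  # 2/3
#' @export
rational <- function(num, den = 1L) {
  if (length(num) != 1L || length(den) != 1L)
    stop("rational() is scalar")
  if (num != round(num) || den != round(den))
    stop("rational() needs integer numerator and denominator")
  num <- as.integer(round(num)); den <- as.integer(round(den))
  if (den == 0L) stop("zero denominator")
  if (den < 0L) { num <- -num; den <- -den }
  g <- .gcd(abs(num), den)
  if (g > 1L) { num <- num %/% g; den <- den %/% g }
  structure(list(num = num, den = den), class = "rational")
}

.gcd <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  max(a, 1L)
}

.as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.numeric(x) && length(x) == 1L && x == round(x))
    return(rational(as.integer(x), 1L))
  stop("cannot coerce to rational: ", deparse(x))
}

#' @export
Ops.rational <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/")) {
    a <- .as_rational(e1); b <- .as_rational(e2)
    switch(.Generic,
      "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
      "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
      "*" = rational(a$num * b$num, a$den * b$den),
      "/" = {
        if (b$num == 0L) stop("division by zero rational")
        rational(a$num * b$den, a$den * b$num)
      })
  } else if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    a <- .as_rational(e1); b <- .as_rational(e2)
    get(.Generic)(a$num * b$den, b$num * a$den)
  } else {
    stop("operation ", .Generic, " not defined for rationals")
  }
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

.rat_num <- function(x) x$num / x$den

#' @export
as.character.rational <- function(x, ...) {
  if (x$den == 1L) as.character(x$num) else paste0(x$num, "/", x$den)
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}
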