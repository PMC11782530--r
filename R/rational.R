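#' Exact rational numbers
#'
#' Minimal vectorised rational arithmetic used for stoichiometric
#' bookkeeping, so that reaction extents and residual-pressure fractions
#' (e.g. 5/9 of the initial moles) are carried exactly rather than as
#' floating point. Numerators and denominators are stored as doubles but
#' are always integral; this is exact up to 2^53, far beyond anything a
#' gas-mixture part table can produce.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero. Recycled against
#'   `num` when either has length one.
#' @return An object of class `rational`.
#' @examples
#' rational(5, 9) + rational(4, 9)
#' as.numeric(rational(5, 3))
#' @export
rational <- function(num, den = 1) {
  if (length(den) == 1L && length(num) > 1L) den <- rep(den, length(num))
  if (length(num) == 1L && length(den) > 1L) num <- rep(num, length(den))
  stopifnot(
    length(num) == length(den),
    all(is.finite(num)), all(is.finite(den)), all(den != 0),
    all(num == round(num)), all(den == round(den))
  )
  num <- unname(num)
  den <- unname(den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

.gcd1 <- function(a, b) {
  while (b != 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

.gcd <- function(a, b) {
  if (length(a) == 0L) return(numeric(0))
  mapply(.gcd1, a, b)
}

#' Coerce to rational
#'
#' Integral values and short decimals (part tables such as 7:1:1 or the
#' feed fraction 0.11392) are represented exactly with a power-of-ten
#' denominator; anything else is approximated to nine decimal places,
#' which is ample for normalised GC fractions while keeping the exact
#' path exact.
#'
#' @param x a `rational` or numeric vector.
#' @return A `rational` vector.
#' @export
as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  stopifnot(is.numeric(x), all(is.finite(x)))
  den <- vapply(x, function(xi) {
    for (k in 0:8) {
      scaled <- xi * 10^k
      if (abs(scaled - round(scaled)) < 1e-9 * max(1, abs(scaled))) return(10^k)
    }
    1e9
  }, numeric(1))
  rational(round(x * den), den)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational")
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  n1 <- e1$num; d1 <- e1$den
  n2 <- e2$num; d2 <- e2$den
  switch(.Generic,
    "+" = rational(n1 * d2 + n2 * d1, d1 * d2),
    "-" = rational(n1 * d2 - n2 * d1, d1 * d2),
    "*" = rational(n1 * n2, d1 * d2),
    "/" = {
      if (any(n2 == 0)) stop("division by zero rational")
      rational(n1 * d2, d1 * n2)
    },
    "==" = n1 * d2 == n2 * d1,
    "!=" = n1 * d2 != n2 * d1,
    "<"  = n1 * d2 < n2 * d1,
    "<=" = n1 * d2 <= n2 * d1,
    ">"  = n1 * d2 > n2 * d1,
    ">=" = n1 * d2 >= n2 * d1,
    stop(.Generic, " not defined for rational")
  )
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, as.character(x$num), paste0(x$num, "/", x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Sum of a rational vector (exact)
#' @param x a `rational` vector.
#' @return A length-one `rational`.
#' @export
rational_sum <- function(x) {
  out <- rational(0, 1)
  for (i in seq_len(length(x))) out <- out + x[i]
  out
}

# index of the exact minimum (first on ties)
.rational_which_min <- function(x) {
  idx <- 1L
  for (i in seq_len(length(x))[-1]) if (x[i] < x[idx]) idx <- i
  idx
}
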