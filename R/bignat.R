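## Exact non-negative big-integer arithmetic for library diversities.
## Numbers are stored little-endian in base 1e4 digit vectors; the only
## operations needed are multiplication by small integers (per-position
## amino-acid multiplicities), so no general bignum machinery is required.

.BN_BASE <- 1e4

#' Exact non-negative big integer
#'
#' Constructs an arbitrary-precision non-negative integer used to hold
#' combinatorial library diversities (e.g. 5^22 * 6^34 * 8^12, a 53-digit
#' number) without floating-point overflow or rounding.
#'
#' @param x a single non-negative integer-valued number below 2^53.
#' @return An object of class \code{bignat}.
#' @examples
#' bignat(1)
#' bignat(12345) * 10L
#' @export
bignat <- function(x) {
  if (inherits(x, "bignat")) return(x)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("'x' must be a single non-negative integer")
  if (x >= 2^53) stop("'x' too large for exact conversion; build by multiplication")
  digits <- numeric(0)
  repeat {
    digits <- c(digits, x %% .BN_BASE)
    x <- x %/% .BN_BASE
    if (x == 0) break
  }
  structure(list(digits = digits), class = "bignat")
}

## multiply by a small integer k (k * 9999 + carry must stay exact in doubles)
.bnMulSmall <- function(b, k) {
  if (k < 0 || k != floor(k) || k >= 1e8) stop("multiplier out of range")
  if (k == 0) return(bignat(0))
  v <- b$digits * k
  carry <- 0
  for (i in seq_along(v)) {
    t <- v[i] + carry
    v[i] <- t %% .BN_BASE
    carry <- t %/% .BN_BASE
  }
  while (carry > 0) {
    v <- c(v, carry %% .BN_BASE)
    carry <- carry %/% .BN_BASE
  }
  structure(list(digits = v), class = "bignat")
}

#' @export
`*.bignat` <- function(e1, e2) {
  if (inherits(e2, "bignat")) { tmp <- e1; e1 <- e2; e2 <- tmp }
  .bnMulSmall(e1, as.numeric(e2))
}

#' @export
as.character.bignat <- function(x, ...) {
  d <- rev(x$digits)
  paste0(d[1L], paste(sprintf("%04d", d[-1L]), collapse = ""))
}

#' @export
as.double.bignat <- function(x, ...) as.numeric(as.character(x))

#' @export
format.bignat <- function(x, ...) as.character(x)

#' @export
print.bignat <- function(x, ...) {
  cat("<bignat> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' Scientific-notation rendering of a big integer
#'
#' Rounds an exact big integer to a given number of significant figures and
#' renders it in scientific notation, e.g. a 53-digit diversity becomes
#' \code{"5e+52"} at one significant figure.
#'
#' @param x a \code{bignat} (or a number coercible to one).
#' @param digits number of significant figures (default 1).
#' @return A list with elements \code{mantissa} (numeric), \code{exponent}
#'   (integer), \code{string} (e.g. \code{"5e+52"}) and \code{value}
#'   (\code{mantissa * 10^exponent} as a double).
#' @examples
#' sciSignif(bignat(46942), digits = 1)  # "5e+04"
#' @export
sciSignif <- function(x, digits = 1L) {
  x <- bignat(if (is.numeric(x)) x else x)
  s <- as.character(x)
  expo <- nchar(s) - 1L
  if (s == "0") return(list(mantissa = 0, exponent = 0L, string = "0e+00", value = 0))
  keep <- substr(s, 1L, digits)
  nxt <- if (nchar(s) > digits) as.integer(substr(s, digits + 1L, digits + 1L)) else 0L
  mant <- as.numeric(keep)
  if (nxt >= 5L) mant <- mant + 1L
  if (mant >= 10^digits) {  # rounding carried into a new leading digit
    mant <- mant / 10
    expo <- expo + 1L
  }
  mant <- mant / 10^(digits - 1L)
  list(mantissa = mant, exponent = expo,
       string = sprintf("%.*ge+%02d", digits, mant, expo),
       value = mant * 10^expo)
}
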