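## Exact arbitrary-precision non-negative integer arithmetic.
##
## Arrangement counts in the ensemble combinatorics overflow double precision
## already at moderate spine numbers (C(a, b) exceeds 2^53 around a ~ 57), so
## every count in this package is carried as an exact big integer and converted
## to a floating ratio only at the boundary of each operation.
##
## Representation: numeric vector of base-1e6 limbs, little-endian (limb 1 is
## the least significant). Base 1e6 keeps every intermediate product and carry
## exactly representable in a double (products < 1e12, convolution sums safe
## for numbers with up to ~9000 limbs). Objects carry S3 class "exactint".

.BI_BASE <- 1e6

bi_new <- function(limbs) {
  structure(as.numeric(limbs), class = "exactint")
}

## carry-propagate and strip leading zero limbs
bi_norm <- function(v) {
  v <- as.numeric(v)
  i <- 1L
  while (i <= length(v)) {
    if (v[i] >= .BI_BASE) {
      carry <- v[i] %/% .BI_BASE
      v[i] <- v[i] - carry * .BI_BASE
      if (i == length(v)) v <- c(v, carry) else v[i + 1L] <- v[i + 1L] + carry
    }
    i <- i + 1L
  }
  n <- length(v)
  while (n > 1L && v[n] == 0) n <- n - 1L
  bi_new(v[seq_len(n)])
}

## from a non-negative integer-valued double < 2^53
bi_from_num <- function(x) {
  stopifnot(is.finite(x), x >= 0, x == floor(x))
  if (x == 0) return(bi_new(0))
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .BI_BASE)
    x <- floor(x / .BI_BASE)
  }
  bi_new(limbs)
}

as_bi <- function(x) {
  if (inherits(x, "exactint")) x else bi_from_num(x)
}

bi_is_zero <- function(a) length(a) == 1L && a[1] == 0

bi_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  v <- numeric(n)
  v[seq_len(la)] <- unclass(a)
  v[seq_len(lb)] <- v[seq_len(lb)] + unclass(b)
  bi_norm(v)
}

## a - b, requires a >= b
bi_sub <- function(a, b) {
  stopifnot(bi_cmp(a, b) >= 0)
  la <- length(a)
  v <- numeric(la)
  v[seq_len(la)] <- unclass(a)
  v[seq_len(length(b))] <- v[seq_len(length(b))] - unclass(b)
  for (i in seq_len(la - 1L)) {
    if (v[i] < 0) {
      borrow <- ceiling(-v[i] / .BI_BASE)
      v[i] <- v[i] + borrow * .BI_BASE
      v[i + 1L] <- v[i + 1L] - borrow
    }
  }
  n <- la
  while (n > 1L && v[n] == 0) n <- n - 1L
  bi_new(v[seq_len(n)])
}

## multiply by a small non-negative integer (< 2^31)
bi_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == floor(s))
  if (s == 0 || bi_is_zero(a)) return(bi_new(0))
  bi_norm(unclass(a) * s)
}

## schoolbook product
bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(bi_new(0))
  la <- length(a); lb <- length(b)
  v <- numeric(la + lb)
  ua <- unclass(a); ub <- unclass(b)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    v[idx] <- v[idx] + ua[i] * ub
    ## keep partial sums well inside exact-double range
    if (i %% 64L == 0L) v <- unclass(bi_pad(bi_norm(v), la + lb))
  }
  bi_norm(v)
}

bi_pad <- function(a, n) {
  v <- numeric(n)
  v[seq_along(a)] <- unclass(a)
  bi_new(v)
}

## exact division by a small positive integer; errors if not divisible
bi_div_small <- function(a, s, exact = TRUE) {
  stopifnot(s >= 1, s == floor(s))
  ua <- unclass(a)
  q <- numeric(length(ua))
  r <- 0
  for (i in rev(seq_along(ua))) {
    cur <- r * .BI_BASE + ua[i]
    q[i] <- floor(cur / s)
    r <- cur - q[i] * s
  }
  if (exact && r != 0) stop("non-exact division in big-integer arithmetic")
  n <- length(q)
  while (n > 1L && q[n] == 0) n <- n - 1L
  bi_new(q[seq_len(n)])
}

## -1, 0, 1 for a < b, a == b, a > b
bi_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(sign(la - lb))
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

bi_to_double <- function(a) {
  ua <- unclass(a)
  ## most-significant first so that small trailing limbs are not lost to
  ## rounding before the magnitude is established
  x <- 0
  for (i in rev(seq_along(ua))) {
    x <- x * .BI_BASE + ua[i]
    if (!is.finite(x)) return(Inf)
  }
  x
}

bi_to_string <- function(a) {
  ua <- rev(unclass(a))
  paste0(ua[1], paste(sprintf("%06d", ua[-1]), collapse = ""))
}

## ratio a / b as a double, accurate to ~1e-15 relative even when both
## operands overflow double range: align by limb shifts first
bi_ratio <- function(a, b) {
  if (bi_is_zero(b)) stop("zero denominator")
  if (bi_is_zero(a)) return(0)
  top <- function(x, k = 9L) {
    n <- length(x)
    use <- x[max(1L, n - k + 1L):n]
    val <- 0
    for (i in rev(seq_along(use))) val <- val * .BI_BASE + use[i]
    list(val = val, exp = max(0L, n - k))
  }
  ta <- top(a); tb <- top(b)
  (ta$val / tb$val) * .BI_BASE^(ta$exp - tb$exp)
}

## exact binomial coefficient as big integer, with the vanishing convention
## C(a, b) = 0 for b < 0, b > a or a < 0
bi_choose <- function(a, b) {
  if (b < 0 || a < 0 || b > a) return(bi_new(0))
  b <- min(b, a - b)
  res <- bi_from_num(1)
  if (b == 0) return(res)
  for (i in seq_len(b)) {
    res <- bi_mul_small(res, a - b + i)
    res <- bi_div_small(res, i)
  }
  res
}

#' @export
format.exactint <- function(x, ...) bi_to_string(x)

#' @export
print.exactint <- function(x, ...) {
  cat(bi_to_string(x), "\n")
  invisible(x)
}

#' @export
as.character.exactint <- function(x, ...) bi_to_string(x)

#' @export
as.double.exactint <- function(x, ...) bi_to_double(x)

#' Exact binomial coefficient
#'
#' Computes the binomial coefficient \eqn{C(a, b)} exactly, as an
#' arbitrary-precision integer. Impossible coefficients (\eqn{b < 0},
#' \eqn{b > a}, \eqn{a < 0}) are 0; the end-correction terms of the ensemble
#' placement counts rely on this vanishing convention.
#'
#' @param a,b single non-negative integers (vanishing cases excepted).
#' @return An object of class \code{"exactint"}; coerce with
#'   \code{as.character} (exact decimal digits) or \code{as.numeric}.
#' @examples
#' exactChoose(30, 5)          # 142506
#' as.numeric(exactChoose(4, 2))
#' @export
exactChoose <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L,
            a == floor(a), b == floor(b))
  bi_choose(a, b)
}
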