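# Arbitrary-precision non-negative integers and exact rationals.
#
# Optima counts routinely exceed 2^53 (counts of 1e90+ occur on real
# supertree datasets), and tie detection / consensus thresholds must be
# exact, so all counting and all frequency comparisons go through these
# routines.  Representation: little-endian numeric vector of limbs in
# base 1e7; all limb products stay well below 2^53.

.BIG_BASE <- 1e7

big_norm <- function(x) {
  # carry-propagate and strip leading (high-order) zero limbs
  i <- 1L
  while (i <= length(x)) {
    if (x[i] >= .BIG_BASE) {
      carry <- floor(x[i] / .BIG_BASE)
      x[i] <- x[i] - carry * .BIG_BASE
      if (i == length(x)) x <- c(x, 0)
      x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

#' Construct a big integer
#'
#' Exact non-negative integer of unbounded size, used for counts of optimal
#' trees.  Accepts a non-negative double below 2^53, a decimal string, or an
#' existing `bigcount`.
#'
#' @param x a non-negative integer-valued number, a decimal string, or a
#'   `bigcount`.
#' @return an object of class `bigcount`.
#' @examples
#' bigcount("77000000000000000000000000000000") * bigcount(10)
#' @export
bigcount <- function(x) {
  if (inherits(x, "bigcount")) return(x)
  if (is.character(x)) return(big_from_string(x))
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0, x == floor(x))
  if (x > 2^53) stop("numeric input too large to be exact; pass a string")
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- floor(x / .BIG_BASE)
    if (x == 0) break
  }
  if (length(limbs) == 0L) limbs <- 0
  structure(big_norm(limbs), class = "bigcount")
}

big_from_string <- function(s) {
  s <- gsub("[ ,_]", "", s)
  stopifnot(grepl("^[0-9]+$", s))
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  nd <- nchar(s)
  limbs <- numeric(ceiling(nd / 7))
  for (i in seq_along(limbs)) {
    hi <- nd - 7L * (i - 1L)
    lo <- max(1L, hi - 6L)
    limbs[i] <- as.numeric(substr(s, lo, hi))
  }
  structure(big_norm(limbs), class = "bigcount")
}

big_is_zero <- function(a) length(unclass(a)) == 1L && unclass(a)[1L] == 0

big_add <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- max(length(a), length(b))
  x <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  structure(big_norm(x), class = "bigcount")
}

# a - b, requires a >= b
big_sub <- function(a, b) {
  if (big_cmp(a, b) < 0) stop("big_sub: negative result")
  a <- unclass(a); b <- unclass(b)
  x <- c(a, numeric(0))
  b <- c(b, numeric(length(a) - length(b)))
  borrow <- 0
  for (i in seq_along(x)) {
    d <- x[i] - b[i] - borrow
    if (d < 0) { d <- d + .BIG_BASE; borrow <- 1 } else borrow <- 0
    x[i] <- d
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  structure(x, class = "bigcount")
}

big_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if ((length(a) == 1L && a[1L] == 0) || (length(b) == 1L && b[1L] == 0))
    return(bigcount(0))
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
    # immediate carry pass keeps partial sums < 2^53
    res <- c(res, 0)
    for (j in idx) {
      if (res[j] >= .BIG_BASE) {
        carry <- floor(res[j] / .BIG_BASE)
        res[j] <- res[j] - carry * .BIG_BASE
        res[j + 1L] <- res[j + 1L] + carry
      }
    }
    res <- big_norm(res)
    res <- c(res, numeric(max(0L, length(a) + length(b) - length(res))))
  }
  structure(big_norm(res), class = "bigcount")
}

# sign of a - b: -1, 0, 1
big_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

# multiply by a small non-negative integer q < 1e7
big_mul_small <- function(a, q) {
  stopifnot(q >= 0, q < .BIG_BASE)
  if (q == 0) return(bigcount(0))
  structure(big_norm(unclass(a) * q), class = "bigcount")
}

# exact quotient and remainder; b > 0
big_divmod <- function(a, b) {
  if (big_is_zero(b)) stop("division by zero")
  if (big_cmp(a, b) < 0) return(list(q = bigcount(0), r = a))
  av <- unclass(a)
  q <- numeric(length(av))
  r <- bigcount(0)
  for (i in rev(seq_along(av))) {
    # r <- r * BASE + limb_i
    rv <- unclass(r)
    if (length(rv) == 1L && rv[1L] == 0) rv <- numeric(0)
    r <- structure(big_norm(c(av[i], rv)), class = "bigcount")
    if (big_cmp(r, b) < 0) { q[i] <- 0; next }
    lo <- 0; hi <- .BIG_BASE - 1
    while (lo < hi) {        # binary search for the limb quotient
      mid <- ceiling((lo + hi) / 2)
      if (big_cmp(big_mul_small(b, mid), r) <= 0) lo <- mid else hi <- mid - 1
    }
    q[i] <- lo
    r <- big_sub(r, big_mul_small(b, lo))
  }
  list(q = structure(big_norm(q), class = "bigcount"), r = r)
}

#' @export
as.character.bigcount <- function(x, ...) {
  v <- unclass(x)
  out <- formatC(v[length(v)], format = "d")
  if (length(v) > 1L) {
    rest <- vapply(rev(v[-length(v)]), function(d) formatC(d, width = 7, flag = "0", format = "d"), "")
    out <- paste0(out, paste(rest, collapse = ""))
  }
  out
}

#' @export
format.bigcount <- function(x, ...) as.character(x)

#' @export
print.bigcount <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
as.double.bigcount <- function(x, ...) {
  v <- unclass(x)
  sum(v * .BIG_BASE^(seq_along(v) - 1))
}

#' @export
`+.bigcount` <- function(e1, e2) big_add(bigcount(e1), bigcount(e2))

#' @export
`*.bigcount` <- function(e1, e2) big_mul(bigcount(e1), bigcount(e2))

#' @export
`==.bigcount` <- function(e1, e2) big_cmp(bigcount(e1), bigcount(e2)) == 0L

# ---- exact non-negative rationals (num/den, not reduced) ----

rat <- function(num, den) {
  num <- bigcount(num); den <- bigcount(den)
  if (big_is_zero(den)) stop("rational with zero denominator")
  list(num = num, den = den)
}

# sign of r1 - r2 via cross multiplication
rat_cmp <- function(r1, r2) big_cmp(big_mul(r1$num, r2$den), big_mul(r2$num, r1$den))

rat_eq_one <- function(r) big_cmp(r$num, r$den) == 0L

rat_to_double <- function(r) {
  n <- unclass(r$num); d <- unclass(r$den)
  # align leading limbs so both convert without overflow
  k <- max(length(n), length(d)) - 4L
  if (k > 0L) {
    n <- n[-seq_len(min(k, length(n) - 1L))]
    d <- d[-seq_len(min(k, length(d) - 1L))]
  }
  sum(n * .BIG_BASE^(seq_along(n) - 1)) / sum(d * .BIG_BASE^(seq_along(d) - 1))
}

# fixed-point decimal string, round half up
rat_decimal <- function(r, digits = 6L) {
  scale <- bigcount(10^digits)
  qd <- big_divmod(big_mul(r$num, scale), r$den)
  q <- qd$q
  if (big_cmp(big_add(qd$r, qd$r), r$den) >= 0L) q <- big_add(q, bigcount(1))
  s <- as.character(q)
  if (nchar(s) <= digits) s <- paste0(strrep("0", digits - nchar(s) + 1L), s)
  paste0(substr(s, 1L, nchar(s) - digits), ".", substr(s, nchar(s) - digits + 1L, nchar(s)))
}

# exact rational representation of a double in [0, 1): p / 2^e
rat_from_double <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x < 1)
  p <- x
  two_e <- bigcount(1)
  for (i in 0:1100) {
    if (p == floor(p)) return(rat(bigcount(p), two_e))
    if (p <= 2^52) p <- p * 2
    two_e <- big_add(two_e, two_e)
  }
  stop("cannot represent threshold exactly")
}
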