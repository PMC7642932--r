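# Minimal non-negative big-integer layer used by the exact Stirling oracle.
# Numbers are stored as little-endian digit vectors in base 1e7 (doubles);
# digit * multiplier stays far below 2^53 for the multipliers used here
# (row index n <= 250, rational numerator/denominator of theta).

.BI_BASE <- 1e7

bi_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  d
}

# propagate carries; d may have entries >= base after add/scale
bi_normalize <- function(d) {
  repeat {
    carry <- floor(d / .BI_BASE)
    if (all(carry == 0)) break
    d <- d - carry * .BI_BASE
    carry <- c(0, carry)
    if (length(carry) > length(d)) d <- c(d, 0)
    d <- d + carry
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_normalize(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiply by a small non-negative integer scalar (< ~9e8 keeps digit*s < 2^53)
bi_smul <- function(a, s) {
  stopifnot(s >= 0, s == floor(s), s < 9e8)
  if (s == 0) return(0)
  bi_normalize(a * s)
}

bi_is_zero <- function(a) length(a) == 1L && a[1] == 0

# exact when the value is below 2^53; otherwise best double approximation
# (may overflow to Inf for very large values -- use bi_log then)
bi_to_double <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * .BI_BASE + a[i]
  v
}

# natural log of a positive big integer, accurate to double precision
bi_log <- function(a) {
  if (bi_is_zero(a)) return(-Inf)
  k <- length(a)
  # use the top few digits (>= 17 significant decimal digits)
  top <- min(k, 4L)
  mant <- 0
  for (i in seq(k, k - top + 1L)) mant <- mant * .BI_BASE + a[i]
  log(mant) + (k - top) * log(.BI_BASE)
}

bi_to_string <- function(a) {
  if (bi_is_zero(a)) return("0")
  digs <- sprintf("%07.0f", a[-length(a)])
  paste0(sprintf("%.0f", a[length(a)]), paste(rev(digs), collapse = ""))
}
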