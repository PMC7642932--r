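# Stirling numbers of the first kind.
#
# The signed number S_n(k) is the coefficient in the rising-factorial
# expansion (theta)_n = sum_k (-1)^(n-k) S_n(k) theta^k; the unsigned
# magnitude c(n, k) = |S_n(k)| counts permutations of n elements with k
# cycles and obeys c(n+1, k) = c(n, k-1) + n c(n, k) with all addends
# non-negative, so the whole row can be accumulated in log space without
# cancellation or overflow.

# practical ceiling for the O(n^2) exact engines
.STIRLING_MAX_N <- 20000L
.BIG_STIRLING_MAX_N <- 250L

.row_cache <- new.env(parent = emptyenv())

#' Row of unsigned Stirling numbers of the first kind, in log space
#'
#' Computes `ln c(n, k)` for `k = 0, ..., n`, where `c(n, k)` is the unsigned
#' Stirling number of the first kind (the magnitude of the signed number
#' `S_n(k) = (-1)^(n-k) c(n, k)`). The row is built iteratively from row 1 by
#' the recurrence `c(n+1, k) = c(n, k-1) + n c(n, k)`, keeping a single row in
#' memory, so rows for `n` in the thousands are computed without overflow.
#'
#' @param n Positive integer row index (number of sequences). Rows above
#'   `n = 20000` are refused: the recurrence is O(n^2) and the package treats
#'   that as the practical ceiling of the exact engine.
#' @return Numeric vector of length `n + 1`; entry `k + 1` holds `ln c(n, k)`.
#'   Entry 1 (i.e. `k = 0`) is `-Inf` for all `n >= 1` since `c(n, 0) = 0`.
#'   Rows are memoised per `n` within the session.
#' @examples
#' exp(log_stirling_row(10)[6]) # |S_10(5)| = 269325
#' @export
log_stirling_row <- function(n) {
  n <- assert_count(n, "n")
  if (n > .STIRLING_MAX_N) {
    stop("log_stirling_row(): n = ", n, " exceeds the exact-engine ceiling of ",
         .STIRLING_MAX_N, " (O(n^2) recurrence)", call. = FALSE)
  }
  key <- as.character(n)
  if (!is.null(.row_cache[[key]])) return(.row_cache[[key]])
  lr <- c(-Inf, 0)
  if (n > 1L) {
    for (nn in seq_len(n - 1L)) {
      # c(nn+1, k) = c(nn, k-1) + nn * c(nn, k), k = 0..nn+1
      lr <- logaddexp(c(-Inf, lr), c(lr + log(nn), -Inf))
    }
  }
  .row_cache[[key]] <- lr
  lr
}

# exact big-integer rows c(n, .), cached as list-of-bigints
.big_row_cache <- new.env(parent = emptyenv())

big_stirling_row <- function(n) {
  n <- assert_count(n, "n")
  key <- as.character(n)
  if (!is.null(.big_row_cache[[key]])) return(.big_row_cache[[key]])
  row <- list(0, 1)           # row 1: c(1,0)=0, c(1,1)=1
  if (n > 1L) {
    for (nn in seq_len(n - 1L)) {
      new <- vector("list", nn + 2L)
      for (k in seq_len(nn + 2L)) {
        lower <- if (k >= 2L) row[[k - 1L]] else 0
        same <- if (k <= nn + 1L) bi_smul(row[[k]], nn) else 0
        new[[k]] <- bi_add(lower, same)
      }
      row <- new
    }
  }
  .big_row_cache[[key]] <- row
  row
}

#' Signed Stirling number of the first kind, exact integer arithmetic
#'
#' Exact evaluation of `S_n(k) = (-1)^(n-k) c(n, k)` via the integer
#' recurrence, carried out in arbitrary-precision (base-1e7 digit) arithmetic.
#' This is the validation oracle for [log_stirling_row()]; it is intended for
#' modest `n` (the numbers have hundreds of digits already at `n = 200`).
#'
#' @param n Positive integer, `n <= 250`.
#' @param k Integer in `[0, n]`.
#' @return An object of class `stirling_integer` holding the exact value;
#'   `as.numeric()` gives the (possibly rounded) double, `as.character()` and
#'   `format()` the exact decimal string.
#' @examples
#' as.numeric(stirling_first_kind(10, 5)) # -269325
#' format(stirling_first_kind(6, 1))      # "-120"
#' @export
stirling_first_kind <- function(n, k) {
  n <- assert_count(n, "n")
  if (n > .BIG_STIRLING_MAX_N) {
    stop("stirling_first_kind(): exact integer path is limited to n <= ",
         .BIG_STIRLING_MAX_N, call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 0 || k > n) {
    stop("stirling_first_kind(): k must be an integer in [0, n]", call. = FALSE)
  }
  mag <- big_stirling_row(n)[[k + 1L]]
  structure(
    list(magnitude = mag, sign = if (bi_is_zero(mag)) 0L else (-1L)^((n - k) %% 2L),
         n = n, k = k),
    class = "stirling_integer"
  )
}

#' @export
as.double.stirling_integer <- function(x, ...) x$sign * bi_to_double(x$magnitude)

#' @export
as.character.stirling_integer <- function(x, ...) {
  paste0(if (x$sign < 0) "-" else "", bi_to_string(x$magnitude))
}

#' @export
format.stirling_integer <- function(x, ...) as.character(x)

#' @export
print.stirling_integer <- function(x, ...) {
  cat(sprintf("S_%d(%d) = %s\n", x$n, x$k, as.character(x)))
  invisible(x)
}

# log of the unsigned magnitude, for cross-checks against log_stirling_row
log_abs_stirling_integer <- function(x) bi_log(x$magnitude)

# shared argument checks ----------------------------------------------------

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(name, " must be a single integer >= 1", call. = FALSE)
  }
  as.integer(x)
}

assert_params <- function(n, m, theta) {
  n <- assert_count(n, "n")
  m <- assert_count(m, "m")
  if (m > n) stop("m must satisfy 1 <= m <= n", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single positive number", call. = FALSE)
  }
  list(n = n, m = m, theta = as.numeric(theta))
}
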