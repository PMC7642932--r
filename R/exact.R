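# Exact engine for the Ewens tail probability and Fu's Fs.
#
# All addends (-1)^(n-k) S_n(k) theta^k of the Ewens normalising sum are
# non-negative, so S' and T' are ratios of partial log-sum-exps over the same
# term set l_k = ln c(n, k) + k ln theta. Forming both tails from the same
# partials makes S' + T' = 1 by construction and gives a cancellation-free
# Fs = ln(S'/T') as a plain difference of two log partial sums.

# log partial sums of the Ewens term set for one (n, m, theta)
fs_partials <- function(n, m, theta) {
  lr <- log_stirling_row(n)
  lk <- lr + (0:n) * log(theta)
  log_upper <- logsumexp(lk[(m + 1L):(n + 1L)])  # k = m..n
  log_lower <- if (m >= 1L) logsumexp(lk[seq_len(m)]) else -Inf  # k < m
  list(log_upper = log_upper, log_lower = log_lower,
       log_total = logaddexp(log_upper, log_lower))
}

#' Ewens tail probability S'(n, m, theta)
#'
#' Probability that at least `m` distinct alleles are observed in a sample of
#' `n` sequences under the Ewens sampling formula with diversity `theta`.
#' Computed exactly (to floating precision) in log space; no overflow for any
#' `n` up to the engine ceiling of 20000.
#'
#' @param n Sample size (number of sequences), integer `>= 1`.
#' @param m Observed number of distinct alleles, integer in `[1, n]`.
#' @param theta Positive diversity parameter (average pairwise difference).
#' @return A probability in `[0, 1]`; 1 when `m = 1`.
#' @examples
#' s_prime(3, 3, 2) # 2^3 / (2*3*4) = 1/3
#' @export
s_prime <- function(n, m, theta) {
  p <- assert_params(n, m, theta)
  parts <- fs_partials(p$n, p$m, p$theta)
  if (parts$log_lower <= parts$log_upper) {
    exp(parts$log_upper - parts$log_total)
  } else {
    1 - exp(parts$log_lower - parts$log_total)
  }
}

#' Complementary Ewens probability T'(n, m, theta)
#'
#' `T' = 1 - S'` computed directly from its own partial sum over `k < m`, so
#' it keeps full relative accuracy when `S'` is close to 1 (where forming
#' `1 - S'` would cancel).
#'
#' @inheritParams s_prime
#' @return A probability in `[0, 1]`; 0 when `m = 1`.
#' @examples
#' t_prime(100, 31, 39.37)
#' @export
t_prime <- function(n, m, theta) {
  p <- assert_params(n, m, theta)
  parts <- fs_partials(p$n, p$m, p$theta)
  if (parts$log_lower <= parts$log_upper) {
    exp(parts$log_lower - parts$log_total)
  } else {
    1 - exp(parts$log_upper - parts$log_total)
  }
}

# fs_result constructor shared by both engines
new_fs_result <- function(n, m, theta, s_prime, t_prime, fs, branch, method,
                          diagnostics = list()) {
  structure(
    list(n = n, m = m, theta = theta, s_prime = s_prime, t_prime = t_prime,
         fs = fs, branch = branch, method = method, diagnostics = diagnostics),
    class = "fs_result"
  )
}

#' Exact Fu's Fs
#'
#' Fu's Fs is the logit of the Ewens tail probability,
#' `Fs = ln(S'/(1 - S'))`. The exact engine evaluates both log partial sums of
#' the Ewens term set and returns `Fs` as their difference, which is free of
#' cancellation on either side of `S' = 1/2`. The branch label records which
#' of the two equivalent relations (the `S'`-form or the complementary
#' `T'`-form) is the numerically natural one, i.e. which tail carries less
#' mass; ties at `S' = 1/2` are labelled as the T-branch.
#'
#' @inheritParams s_prime
#' @return An object of class `fs_result` with fields `s_prime`, `t_prime`,
#'   `fs`, `branch` (`"S-branch"`, `"T-branch"` or `"closed-form"`), `method`
#'   (`"exact"`) and a `diagnostics` list with the log partial sums. For the
#'   degenerate `m = 1` the statistic is `+Inf` (flagged `"closed-form"`), not
#'   an error.
#' @examples
#' fu_fs_exact(25, 20, 9.39)
#' @export
fu_fs_exact <- function(n, m, theta) {
  p <- assert_params(n, m, theta)
  if (p$m == 1L) {
    return(new_fs_result(p$n, p$m, p$theta, s_prime = 1, t_prime = 0, fs = Inf,
                         branch = "closed-form", method = "exact",
                         diagnostics = list(degenerate = "m = 1: S' = 1 exactly")))
  }
  parts <- fs_partials(p$n, p$m, p$theta)
  fs <- parts$log_upper - parts$log_lower
  if (parts$log_lower <= parts$log_upper) {
    tp <- exp(parts$log_lower - parts$log_total)
    sp <- 1 - tp
    branch <- "T-branch"
  } else {
    sp <- exp(parts$log_upper - parts$log_total)
    tp <- 1 - sp
    branch <- "S-branch"
  }
  new_fs_result(p$n, p$m, p$theta, sp, tp, fs, branch, "exact",
                diagnostics = list(log_s_partial = parts$log_upper,
                                   log_t_partial = parts$log_lower))
}

# ---------------------------------------------------------------------------
# Independent rational oracle (tests only): evaluates the Ewens sums with
# exact big-integer arithmetic for rational theta = p/q. Multiplying the sum
# through by q^n makes every term c(n,k) p^k q^(n-k) an exact integer; the
# log partial sums are then read off with bi_log.
fs_partials_rational <- function(n, m, p_num, q_den) {
  row <- big_stirling_row(n)
  upper <- 0
  lower <- 0
  for (k in 0:n) {
    term <- row[[k + 1L]]
    if (bi_is_zero(term)) next
    for (i in seq_len(k)) term <- bi_smul(term, p_num)
    for (i in seq_len(n - k)) term <- bi_smul(term, q_den)
    if (k >= m) upper <- bi_add(upper, term) else lower <- bi_add(lower, term)
  }
  list(log_upper = bi_log(upper), log_lower = bi_log(lower))
}
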