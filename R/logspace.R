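# Log-domain arithmetic helpers. All probability mass in this package is
# accumulated in natural-log space; these are the only primitives that touch
# the exp/log boundary.

# elementwise log(exp(a) + exp(b)); -Inf is the additive identity
logaddexp <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  # both -Inf (or hi -Inf) would give NaN above
  out[is.infinite(hi) & hi < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b > a) stop("logdiffexp: negative difference", call. = FALSE)
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

# log(1 - exp(a)) for a <= 0, accurate in both tails
log1mexp <- function(a) {
  ifelse(a > -log(2), log(-expm1(a)), log1p(-exp(a)))
}
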