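#' Log of the factorial-to-Pochhammer ratio f_n(theta)
#'
#' The ratio `f_n(theta) = n! * Gamma(theta) / Gamma(theta + n)` rescales the
#' rising factorial `(theta)_n` so that Ewens-formula sums stay inside the
#' floating-point range; `f_n(theta) <= 1` whenever `theta >= 1`. The default
#' path evaluates it through `lgamma`; `method = "recursive"` applies the
#' one-step recursion `f_{n+1} = (n+1)/(n+theta) f_n` and exists as an
#' independent cross-check of the log-gamma path.
#'
#' @param theta Positive scalar diversity parameter.
#' @param n Non-negative integer.
#' @param method `"lgamma"` (default) or `"recursive"`.
#' @return `ln f_n(theta)` as a single double; 0 when `n = 0`.
#' @examples
#' log_pochhammer_ratio(2.5, 5)
#' log_pochhammer_ratio(1, 100) # exactly 0: (1)_n = n!
#' @export
log_pochhammer_ratio <- function(theta, n, method = c("lgamma", "recursive")) {
  method <- match.arg(method)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  if (n == 0) return(0)
  if (method == "lgamma") {
    lgamma(n + 1) + lgamma(theta) - lgamma(theta + n)
  } else {
    # ln f_{k+1} = ln f_k + ln(k+1) - ln(k + theta)
    k <- seq_len(n) - 1
    sum(log(k + 1) - log(k + theta))
  }
}

# ln (theta)_n, the rising factorial
log_pochhammer <- function(theta, n) {
  lgamma(theta + n) - lgamma(theta)
}
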