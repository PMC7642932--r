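# Single-evaluation asymptotic estimator for the Ewens tail probability.
#
# The tail S' (in the raised-index frame n' = n - 1, m' = m - 1) is
# approximated by a regularised incomplete beta function plus a first-order
# saddle-point correction:
#
#   S' ~ I_x(m', n' - m' + 1) + e^{-chi(tau)} C(n', m'-1) g(t0),  x = tau/(1+tau)
#
# where z0 is the positive saddle of phi(z) = lnGamma(z+n'+1) - lnGamma(z+1)
# - m' ln z, t0 = m'/(n'-m') is the minimum of chi(t) = n' ln(1+t) - m' ln t,
# and tau solves chi(tau) - chi(t0) = phi(theta) - phi(z0) on the branch with
# sign(tau - t0) = sign(theta - z0). For theta > z0 the complementary tail is
# estimated instead and Fs is formed from it, which keeps full accuracy when
# S' is close to 1.

#' Saddle-point log-ratio function phi and its derivatives
#'
#' `phi(z) = lnGamma(z + n + 1) - lnGamma(z + 1) - m ln z`, the logarithm of
#' the integrand kernel `(z+1)_n / z^m` whose positive saddle `z0` drives the
#' asymptotic estimator. `deriv = 1` uses the digamma function, `deriv = 2`
#' the trigamma function.
#'
#' @param z Positive evaluation point(s).
#' @param n,m Integer parameters of the kernel (theorem frame; passed
#'   literally, no index shift is applied here).
#' @param deriv 0, 1 or 2.
#' @return Numeric vector of the same length as `z`.
#' @export
saddle_phi <- function(z, n, m, deriv = 0L) {
  if (any(!is.finite(z)) || any(z <= 0)) stop("phi: z must be positive", call. = FALSE)
  switch(as.character(deriv),
    "0" = lgamma(z + n + 1) - lgamma(z + 1) - m * log(z),
    "1" = digamma(z + n + 1) - digamma(z + 1) - m / z,
    "2" = trigamma(z + n + 1) - trigamma(z + 1) + m / z^2,
    stop("deriv must be 0, 1 or 2", call. = FALSE)
  )
}

#' Transformed saddle function chi and its derivatives
#'
#' `chi(t) = n ln(1 + t) - m ln t`, the quadratic-form image of `phi` under
#' the saddle-point transformation. For `0 < m < n` it has a unique interior
#' minimum at `t0 = m/(n - m)` and is strictly convex on `(0, t*)` with
#' `t* = sqrt(m)/(sqrt(n) - sqrt(m)) > t0` (beyond `t*` it keeps increasing
#' but concavely, as `(n - m) ln t`).
#'
#' @param t Positive evaluation point(s).
#' @inheritParams saddle_phi
#' @return Numeric vector of the same length as `t`.
#' @export
saddle_chi <- function(t, n, m, deriv = 0L) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("chi: t must be positive", call. = FALSE)
  switch(as.character(deriv),
    "0" = n * log1p(t) - m * log(t),
    "1" = n / (1 + t) - m / t,
    "2" = -n / (1 + t)^2 + m / t^2,
    stop("deriv must be 0, 1 or 2", call. = FALSE)
  )
}

#' Positive saddle point z0 of phi
#'
#' Solves the digamma equation `psi(z + n + 1) - psi(z + 1) - m/z = 0` by a
#' bracketed root find (`phi'` tends to `-Inf` as `z -> 0+` and is eventually
#' positive for `m < n`), polished with Newton steps to a residual below
#' `1e-12 * max(1, m/z0)`. `z0` is also the transition value of `theta` at
#' which `S' = 1/2` and Fu's Fs changes sign.
#'
#' @inheritParams saddle_phi
#' @return The positive root `z0`.
#' @examples
#' solve_saddle_z0(100, 38) # ~ 22.81
#' @export
solve_saddle_z0 <- function(n, m) {
  if (!(m > 0 && m < n)) {
    stop("solve_saddle_z0(): requires 0 < m < n (use closed forms otherwise)",
         call. = FALSE)
  }
  f <- function(z) saddle_phi(z, n, m, deriv = 1L)
  hi <- max(m, 1)
  it <- 0L
  while (f(hi) < 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 200L) stop("solve_saddle_z0(): failed to bracket", call. = FALSE)
  }
  z0 <- stats::uniroot(f, c(1e-10, hi), tol = 1e-12)$root
  # Newton polish against the trigamma derivative
  for (i in 1:4) {
    step <- f(z0) / saddle_phi(z0, n, m, deriv = 2L)
    z0_new <- z0 - step
    if (!is.finite(z0_new) || z0_new <= 0) break
    z0 <- z0_new
    if (abs(step) < 1e-15 * z0) break
  }
  if (abs(f(z0)) > 1e-12 * max(1, m / z0)) {
    stop("solve_saddle_z0(): residual tolerance not met", call. = FALSE)
  }
  z0
}

#' Transformation parameter tau
#'
#' Solves `chi(tau) = chi(t0) + phi(theta) - phi(z0)` for the positive root on
#' the branch selected by `sign(tau - t0) = sign(theta - z0)`; at
#' `theta = z0` the solution is `tau = t0` exactly. Bracketing starts from
#' the local quadratic guess `t0 +/- sqrt(2 * delta / chi''(t0))` and is
#' safeguarded; the root is Newton-polished to a relative residual below
#' `1e-12`.
#'
#' @param n,m Theorem-frame integers with `0 < m < n`.
#' @param theta Positive diversity parameter.
#' @param z0 Optional precomputed saddle point (computed if omitted).
#' @return The positive solution `tau`.
#' @export
solve_tau <- function(n, m, theta, z0 = NULL) {
  if (!(m > 0 && m < n)) stop("solve_tau(): requires 0 < m < n", call. = FALSE)
  if (is.null(z0)) z0 <- solve_saddle_z0(n, m)
  t0 <- m / (n - m)
  delta <- saddle_phi(theta, n, m) - saddle_phi(z0, n, m)
  if (delta < 0) {
    if (delta < -1e-8 * max(1, abs(saddle_phi(z0, n, m)))) {
      stop("solve_tau(): phi(theta) below the saddle minimum", call. = FALSE)
    }
    delta <- 0
  }
  if (delta == 0 || theta == z0) return(t0)
  chi_t0 <- saddle_chi(t0, n, m)
  target <- chi_t0 + delta
  g <- function(t) saddle_chi(t, n, m) - target
  half_width <- sqrt(2 * delta / saddle_chi(t0, n, m, deriv = 2L))
  if (theta < z0) {
    lo <- max(t0 - 1.2 * half_width, t0 * 1e-12)
    it <- 0L
    while (g(lo) < 0) {
      lo <- lo / 2
      it <- it + 1L
      if (it > 2000L) stop("solve_tau(): failed to bracket below t0", call. = FALSE)
    }
    tau <- stats::uniroot(g, c(lo, t0), tol = 1e-14)$root
  } else {
    hi <- t0 + 1.2 * half_width
    it <- 0L
    while (g(hi) < 0) {
      hi <- hi * 2
      it <- it + 1L
      if (it > 2000L) stop("solve_tau(): failed to bracket above t0", call. = FALSE)
    }
    tau <- stats::uniroot(g, c(t0, hi), tol = 1e-14)$root
  }
  for (i in 1:4) {
    d1 <- saddle_chi(tau, n, m, deriv = 1L)
    if (d1 == 0) break
    step <- g(tau) / d1
    tau_new <- tau - step
    # stay on the selected branch
    if (!is.finite(tau_new) || tau_new <= 0 ||
        (theta < z0 && tau_new > t0) || (theta > z0 && tau_new < t0)) break
    tau <- tau_new
    if (abs(step) < 1e-15 * tau) break
  }
  if (abs(g(tau)) > 1e-12 * max(1, abs(target))) {
    stop("solve_tau(): residual tolerance not met", call. = FALSE)
  }
  tau
}

# Assemble the saddle system for theorem-frame (n', m', theta), 0 < m' < n'
build_saddle_system <- function(n_prime, m_prime, theta) {
  z0 <- solve_saddle_z0(n_prime, m_prime)
  t0 <- m_prime / (n_prime - m_prime)
  tau <- solve_tau(n_prime, m_prime, theta, z0 = z0)
  list(n_prime = n_prime, m_prime = m_prime, theta = theta,
       z0 = z0, t0 = t0, tau = tau, x = tau / (1 + tau),
       residuals = c(phi_prime = saddle_phi(z0, n_prime, m_prime, deriv = 1L),
                     tau_eq = saddle_chi(tau, n_prime, m_prime) -
                       saddle_chi(t0, n_prime, m_prime) -
                       (saddle_phi(theta, n_prime, m_prime) -
                          saddle_phi(z0, n_prime, m_prime))))
}

# log of the incomplete-beta main term on the branch implied by theta vs z0:
# S-branch: I_x(m', n'-m'+1); T-branch: I_{1-x}(n'-m'+1, m')
main_term_log <- function(sys, branch = c("S", "T")) {
  branch <- match.arg(branch)
  if (branch == "S") {
    stats::pbeta(sys$x, sys$m_prime, sys$n_prime - sys$m_prime + 1, log.p = TRUE)
  } else {
    stats::pbeta(1 - sys$x, sys$n_prime - sys$m_prime + 1, sys$m_prime, log.p = TRUE)
  }
}

# first-order correction R' = e^{-chi(tau)} C(n', m'-1) g(t0), assembled in
# log space; returns list(log_mag, sign, g_t0, f_t0)
correction_term_parts <- function(sys) {
  n <- sys$n_prime; m <- sys$m_prime
  f_t0 <- sqrt(saddle_chi(sys$t0, n, m, deriv = 2L) /
                 saddle_phi(sys$z0, n, m, deriv = 2L)) / (sys$z0 - sys$theta)
  g_t0 <- f_t0 - 1 / (sys$t0 - sys$tau)
  log_mag <- -saddle_chi(sys$tau, n, m) + lchoose(n, m - 1) + log(abs(g_t0))
  list(log_mag = log_mag, sign = sign(g_t0), g_t0 = g_t0, f_t0 = f_t0)
}

#' First-order saddle-point correction term
#'
#' The correction `R' = e^{-chi(tau)} * C(n, m-1) * g(t0)` added to the
#' incomplete-beta main term, with `g(t0) = f(t0) - 1/(t0 - tau)` and
#' `f(t0) = sqrt(chi''(t0)/phi''(z0)) / (z0 - theta)`. The exponential and the
#' binomial coefficient are combined in log space so the term never overflows.
#'
#' @param n,m Theorem-frame integers with `0 < m < n`.
#' @param theta Positive diversity parameter; must not sit at the transition
#'   `tau = t0` where the two parts of `g` diverge individually.
#' @return The signed correction as a double.
#' @export
correction_term <- function(n, m, theta) {
  sys <- build_saddle_system(n, m, theta)
  if (sys$tau == sys$t0) {
    stop("correction_term(): undefined at the transition theta = z0", call. = FALSE)
  }
  parts <- correction_term_parts(sys)
  parts$sign * exp(parts$log_mag)
}

# near-transition guard width (relative to t0)
.NEAR_TRANSITION_TOL <- 1e-4

#' Asymptotic Fu's Fs
#'
#' Single-evaluation estimator of Fu's Fs: no Stirling numbers are computed.
#' The tail probability in the raised-index frame (`n' = n - 1`,
#' `m' = m - 1`) is approximated by the regularised incomplete beta function
#' plus the first-order saddle-point correction; for `theta` below the
#' transition `z0` the `S'` tail is formed and `Fs = ln(S'/(1 - S'))`, above
#' it the complementary `T'` tail and `Fs = ln((1 - T')/T')`, so the
#' statistic keeps full relative accuracy on both sides.
#'
#' Degenerate cases use closed forms: `m = 1` gives `Fs = +Inf`; `m = n` uses
#' `S' = theta^n / (theta)_n` exactly. In a narrow window around the
#' transition (`|tau - t0| < 1e-4 max(t0, 1)`) the correction term is a
#' difference of two diverging quantities; there the function falls back to
#' the exact engine (when `n` is within its ceiling) and flags it in the
#' diagnostics. Probabilities straying outside `(0, 1)` are clamped and
#' flagged rather than raised.
#'
#' @inheritParams s_prime
#' @return An `fs_result` (see [fu_fs_exact()]) with `method = "asymptotic"`
#'   and diagnostics `z0`, `t0`, `tau`, `x`, `main_term`, `correction`,
#'   `fallback_used`, `clamped` and the solver residuals.
#' @examples
#' fu_fs_asymptotic(25, 20, 9.39) # ~ -6.83168
#' @export
fu_fs_asymptotic <- function(n, m, theta) {
  p <- assert_params(n, m, theta)
  n <- p$n; m <- p$m; theta <- p$theta
  if (m == 1L) {
    return(new_fs_result(n, m, theta, 1, 0, Inf, "closed-form", "asymptotic",
                         diagnostics = list(degenerate = "m = 1: S' = 1 exactly")))
  }
  if (m == n) {
    # single-term tail: S' = theta^n / (theta)_n
    log_s <- n * log(theta) - log_pochhammer(theta, n)
    sp <- exp(log_s)
    fs <- log_s - log1mexp(log_s)
    return(new_fs_result(n, m, theta, sp, 1 - sp, fs, "closed-form", "asymptotic",
                         diagnostics = list(degenerate = "m = n: single-term tail")))
  }
  np <- n - 1L
  mp <- m - 1L
  sys <- build_saddle_system(np, mp, theta)

  if (abs(sys$tau - sys$t0) < .NEAR_TRANSITION_TOL * max(sys$t0, 1)) {
    if (n <= .STIRLING_MAX_N) {
      res <- fu_fs_exact(n, m, theta)
      res$method <- "asymptotic"
      res$diagnostics <- c(res$diagnostics,
                           list(z0 = sys$z0, t0 = sys$t0, tau = sys$tau,
                                fallback_used = TRUE, clamped = FALSE))
      return(res)
    }
    # beyond the exact ceiling: main term only, correction dropped
    warning("near-transition point beyond the exact-engine ceiling: ",
            "using the incomplete-beta main term without correction")
    parts <- list(log_mag = -Inf, sign = 0, g_t0 = NA_real_, f_t0 = NA_real_)
  } else {
    parts <- correction_term_parts(sys)
  }

  clamped <- FALSE
  # probabilities are carried in log space, so arbitrarily small tails are
  # representable; clamping only engages when the first-order sum strays
  # outside (0, 1): a negative sum (NaN from the signed combination) is
  # floored at 1e-300 and a sum >= 1 is capped at 1 - 1e-16
  clamp_log_prob <- function(lp) {
    if (is.nan(lp)) { clamped <<- TRUE; lp <- log(1e-300) }
    if (lp > log1p(-1e-16)) { clamped <<- TRUE; lp <- log1p(-1e-16) }
    lp
  }

  if (theta < sys$z0) {
    branch <- "S-branch"
    lmain <- main_term_log(sys, "S")
    log_s <- if (parts$sign >= 0) logaddexp(lmain, parts$log_mag)
             else logdiffexp_safe(lmain, parts$log_mag)
    log_s <- clamp_log_prob(log_s)
    sp <- exp(log_s)
    tp <- 1 - sp
    fs <- log_s - log1mexp(log_s)
  } else {
    branch <- "T-branch"
    lmain <- main_term_log(sys, "T")
    # T' = main - R'
    log_t <- if (parts$sign <= 0) logaddexp(lmain, parts$log_mag)
             else logdiffexp_safe(lmain, parts$log_mag)
    log_t <- clamp_log_prob(log_t)
    tp <- exp(log_t)
    sp <- 1 - tp
    fs <- log1mexp(log_t) - log_t
  }
  new_fs_result(n, m, theta, sp, tp, fs, branch, "asymptotic",
                diagnostics = list(z0 = sys$z0, t0 = sys$t0, tau = sys$tau,
                                   x = sys$x, main_term = exp(lmain),
                                   correction = parts$sign * exp(parts$log_mag),
                                   fallback_used = FALSE, clamped = clamped,
                                   residuals = sys$residuals))
}

# log(exp(a) - exp(b)) tolerating a slightly negative difference (clamped later)
logdiffexp_safe <- function(a, b) {
  if (b >= a) return(NaN)
  logdiffexp(a, b)
}
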