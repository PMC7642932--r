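# Saddle-point machinery and the incomplete-beta estimator.

test_that("phi derivatives match central differences", {
  # evaluation points sit away from the saddle so phi' is well scaled
  grid <- list(c(5, 20, 7), c(60, 100, 38), c(100, 500, 275))
  for (g in grid) {
    z <- g[1]; n <- g[2]; m <- g[3]
    h <- 1e-4 * z
    expect_equal(saddle_phi(z, n, m, deriv = 1L),
                 (saddle_phi(z + h, n, m) - saddle_phi(z - h, n, m)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(saddle_phi(z, n, m, deriv = 2L),
                 (saddle_phi(z + h, n, m, 1L) - saddle_phi(z - h, n, m, 1L)) / (2 * h),
                 tolerance = 1e-6)
  }
  expect_error(saddle_phi(-1, 10, 3), "positive")
})

test_that("phi is increasing when m = 0", {
  z <- seq(0.5, 50, length.out = 40)
  expect_true(all(diff(saddle_phi(z, 30, 0)) > 0))
})

test_that("chi has its unique minimum at t0 = m/(n-m) and is convex around it", {
  n <- 100; m <- 38; t0 <- m / (n - m)
  expect_equal(saddle_chi(t0, n, m, deriv = 1L), 0, tolerance = 1e-12)
  expect_gt(saddle_chi(0.61, n, m, deriv = 2L), 0)
  # strict convexity holds up to t* = sqrt(m)/(sqrt(n) - sqrt(m)) > t0
  t_star <- sqrt(m) / (sqrt(n) - sqrt(m))
  ts <- seq(0.05, 0.99 * t_star, length.out = 100)
  expect_true(all(saddle_chi(ts, n, m, deriv = 2L) > 0))
  # t0 is the only stationary point on (0, Inf)
  ts_all <- seq(0.05, 10, length.out = 200)
  expect_identical(sum(diff(sign(saddle_chi(ts_all, n, m, deriv = 1L))) != 0), 1L)
  expect_equal(saddle_chi(1, 17, 0), 17 * log(2), tolerance = 1e-14)
  expect_error(saddle_chi(0, 10, 3), "positive")
})

test_that("saddle point z0 reproduces the published transition values", {
  expect_equal(solve_saddle_z0(100, 38), 22.81, tolerance = 5e-4)
  expect_equal(solve_saddle_z0(100, 75), 137.98, tolerance = 5e-5)
  expect_equal(solve_saddle_z0(500, 275), 251.58, tolerance = 5e-5)
})

test_that("z0 meets its residual contract across a parameter sweep", {
  for (n in c(50L, 200L, 500L)) {
    for (frac in c(0.05, 0.3, 0.6, 0.95)) {
      m <- max(1L, round(frac * n))
      if (m >= n) m <- n - 1L
      z0 <- solve_saddle_z0(n, m)
      expect_lte(abs(saddle_phi(z0, n, m, deriv = 1L)), 1e-12 * max(1, m / z0))
    }
  }
  expect_error(solve_saddle_z0(10, 0), "0 < m < n")
  expect_error(solve_saddle_z0(10, 10), "0 < m < n")
})

test_that("tau solves its defining equation on the correct branch", {
  n <- 100; m <- 38
  z0 <- solve_saddle_z0(n, m)
  t0 <- m / (n - m)
  expect_identical(solve_tau(n, m, z0, z0 = z0), t0)  # theta = z0 -> tau = t0
  for (theta in c(10, 40)) {
    tau <- solve_tau(n, m, theta, z0 = z0)
    expect_identical(sign(tau - t0), sign(theta - z0))
    resid <- saddle_chi(tau, n, m) - saddle_chi(t0, n, m) -
      (saddle_phi(theta, n, m) - saddle_phi(z0, n, m))
    expect_lte(abs(resid), 1e-10)
  }
})

test_that("tau residuals hold across a broad sweep", {
  for (n in c(50L, 200L, 500L)) {
    for (frac in c(0.05, 0.3, 0.6, 0.95)) {
      m <- min(max(1L, round(frac * n)), n - 1L)
      z0 <- solve_saddle_z0(n, m)
      for (theta in c(1, 10, 100, 500)) {
        tau <- solve_tau(n, m, theta, z0 = z0)
        resid <- saddle_chi(tau, n, m) - saddle_chi(m / (n - m), n, m) -
          (saddle_phi(theta, n, m) - saddle_phi(z0, n, m))
        expect_lte(abs(resid), 1e-10 * max(1, abs(saddle_chi(tau, n, m))))
      }
    }
  }
})

test_that("incomplete-beta main term equals its finite binomial sum", {
  # I_{tau/(1+tau)}(m, n-m+1) = (1+tau)^-n sum_{j=m}^{n} C(n,j) tau^j
  n <- 10; m <- 4; tau <- 0.5
  sys <- list(n_prime = n, m_prime = m, x = tau / (1 + tau))
  direct <- sum(choose(n, m:n) * tau^(m:n)) / (1 + tau)^n
  expect_equal(exp(fufs:::main_term_log(sys, "S")), direct, tolerance = 1e-12)
  # complement identity I_x(p, q) = 1 - I_{1-x}(q, p)
  for (x in c(0.1, 0.45, 0.9)) {
    for (pq in list(c(3, 8), c(40, 12))) {
      expect_lt(abs(pbeta(x, pq[1], pq[2]) - (1 - pbeta(1 - x, pq[2], pq[1]))),
                1e-14)
    }
  }
})

test_that("correction term approximates the main-term deficit", {
  # theorem frame n'=99, m'=74 at theta = 50: R' should recover the gap
  # between the exact tail and the incomplete-beta main term to first order
  n_user <- 100; m_user <- 75; theta <- 50
  sys <- fufs:::build_saddle_system(99, 74, theta)
  expect_lt(theta, sys$z0)
  exact_s <- s_prime(n_user, m_user, theta)
  main <- exp(fufs:::main_term_log(sys, "S"))
  r_prime <- correction_term(99, 74, theta)
  expect_equal(r_prime, exact_s - main, tolerance = 0.2)
  expect_error(correction_term(99, 74, sys$z0), "transition")
})

test_that("the correction improves on the main term across theta", {
  n <- 100; m <- 75
  z0 <- solve_saddle_z0(n - 1, m - 1)
  thetas <- seq(10, 400, by = 10)
  thetas <- thetas[abs(thetas - z0) > 0.05 * z0]
  better <- vapply(thetas, function(theta) {
    sys <- fufs:::build_saddle_system(n - 1, m - 1, theta)
    exact <- fu_fs_exact(n, m, theta)
    branch <- if (theta < sys$z0) "S" else "T"
    main <- exp(fufs:::main_term_log(sys, branch))
    ref <- if (branch == "S") exact$s_prime else exact$t_prime
    with_corr <- fu_fs_asymptotic(n, m, theta)
    est <- if (branch == "S") with_corr$s_prime else with_corr$t_prime
    abs(est - ref) <= abs(main - ref)
  }, logical(1))
  expect_gte(mean(better), 0.95)
})

test_that("estimator is continuous across the branch switch at theta = z0", {
  for (nm in list(c(100L, 75L), c(500L, 275L))) {
    n <- nm[1]; m <- nm[2]
    z0 <- solve_saddle_z0(n - 1L, m - 1L)
    eps <- 0.01 * z0
    lo <- fu_fs_asymptotic(n, m, z0 - eps)
    hi <- fu_fs_asymptotic(n, m, z0 + eps)
    expect_identical(lo$branch, "S-branch")
    expect_identical(hi$branch, "T-branch")
    # the switch introduces no artefact: each side stays within the
    # published error bound of the (continuous) exact statistic
    expect_lte(mollified_error(fu_fs_exact(n, m, z0 - eps)$fs, lo$fs), 1e-3)
    expect_lte(mollified_error(fu_fs_exact(n, m, z0 + eps)$fs, hi$fs), 1e-3)
    # and the two branch formulas agree with each other at the same theta
    for (theta in c(z0 - eps, z0 + eps)) {
      sys <- fufs:::build_saddle_system(n - 1L, m - 1L, theta)
      parts <- fufs:::correction_term_parts(sys)
      r_signed <- parts$sign * exp(parts$log_mag)
      s_form <- exp(fufs:::main_term_log(sys, "S")) + r_signed
      t_form <- exp(fufs:::main_term_log(sys, "T")) - r_signed
      fs_s <- log(s_form / (1 - s_form))
      fs_t <- log((1 - t_form) / t_form)
      expect_lte(mollified_error(fs_s, fs_t), 1e-3)
    }
  }
})

test_that("near-transition points fall back to the exact engine with a flag", {
  n <- 100L; m <- 75L
  z0 <- solve_saddle_z0(n - 1L, m - 1L)
  r <- fu_fs_asymptotic(n, m, z0 * (1 + 1e-9))
  expect_true(r$diagnostics$fallback_used)
  expect_equal(r$fs, fu_fs_exact(n, m, z0 * (1 + 1e-9))$fs, tolerance = 1e-12)
  expect_identical(r$method, "asymptotic")
})

test_that("degenerate m use closed forms", {
  r1 <- fu_fs_asymptotic(60, 1, 4)
  expect_identical(r1$fs, Inf)
  expect_identical(r1$branch, "closed-form")
  rn <- fu_fs_asymptotic(30, 30, 5)
  expect_identical(rn$branch, "closed-form")
  expect_equal(rn$fs, fu_fs_exact(30, 30, 5)$fs, tolerance = 1e-10)
  expect_equal(rn$s_prime, s_prime(30, 30, 5), tolerance = 1e-12)
})

test_that("estimator tracks the exact engine on the benchmark triples", {
  for (row in list(c(25, 20, 9.39), c(250, 67, 8.96), c(2001, 213, 9.03))) {
    fe <- fu_fs_exact(row[1], row[2], row[3])$fs
    fa <- fu_fs_asymptotic(row[1], row[2], row[3])$fs
    expect_lte(mollified_error(fe, fa), 1e-3)
  }
})
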