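#' Fu's Fs for one parameter triple
#'
#' Front door for a single evaluation. `method = "exact"` runs the log-space
#' Stirling-sum engine, `"asymptotic"` the incomplete-beta saddle-point
#' estimator, and `"auto"` (default) picks the exact engine for small samples
#' (`n < exact_max_n`, where it is cheap) and the asymptotic estimator
#' otherwise.
#'
#' @inheritParams s_prime
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_max_n Sample-size threshold used by `"auto"`.
#' @return An `fs_result`; see [fu_fs_exact()] and [fu_fs_asymptotic()].
#' @examples
#' fu_fs(25, 20, 9.39)
#' fu_fs(2001, 213, 9.03, method = "asymptotic")
#' @export
fu_fs <- function(n, m, theta, method = c("auto", "exact", "asymptotic"),
                  exact_max_n = 50L) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (n < exact_max_n) "exact" else "asymptotic"
  }
  switch(method,
         exact = fu_fs_exact(n, m, theta),
         asymptotic = fu_fs_asymptotic(n, m, theta))
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("Fu's Fs (%s, %s)\n", x$method, x$branch))
  cat(sprintf("  n = %d, m = %d, theta = %g\n", x$n, x$m, x$theta))
  cat(sprintf("  S' = %.6g, T' = %.6g\n", x$s_prime, x$t_prime))
  cat(sprintf("  Fs = %.7g\n", x$fs))
  if (isTRUE(x$diagnostics$fallback_used)) {
    cat("  (near-transition fallback to the exact engine)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fu's Fs result into a one-row tibble
#'
#' @param x An `fs_result`.
#' @param ... Unused.
#' @return A one-row tibble with columns `n`, `m`, `theta`, `s_prime`,
#'   `t_prime`, `fs`, `branch`, `method`.
#' @export
tidy.fs_result <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, theta = x$theta,
                 s_prime = x$s_prime, t_prime = x$t_prime, fs = x$fs,
                 branch = x$branch, method = x$method)
}

#' One-row diagnostic summary of a Fu's Fs result
#'
#' @param x An `fs_result`.
#' @param ... Unused.
#' @return A one-row tibble with the saddle diagnostics (`NA` for the exact
#'   engine): `z0`, `tau`, `main_term`, `correction`, `fallback_used`,
#'   `clamped`.
#' @export
glance.fs_result <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    fs = x$fs,
    z0 = d$z0 %||% NA_real_,
    tau = d$tau %||% NA_real_,
    main_term = d$main_term %||% NA_real_,
    correction = d$correction %||% NA_real_,
    fallback_used = d$fallback_used %||% NA,
    clamped = d$clamped %||% NA
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch Fu's Fs over a table of parameter triples
#'
#' Evaluates every row of a data frame with columns `n`, `m`, `theta` and
#' appends the results, so batches pipe naturally:
#' `read_tsv(f) |> fs_batch() |> write_tsv(out)`.
#'
#' @param data Data frame with numeric columns `n`, `m`, `theta`.
#' @param method Passed to [fu_fs()].
#' @param diagnostics If `TRUE`, also append `z0`, `tau`, `main_term`,
#'   `correction`, `fallback_used`.
#' @param exact_max_n Passed to [fu_fs()].
#' @return The input as a tibble with columns `s_prime`, `t_prime`, `fs`,
#'   `branch`, `method` appended (plus diagnostics when requested).
#' @examples
#' fs_batch(data.frame(n = c(25, 50), m = c(20, 31), theta = c(9.39, 9.61)))
#' @export
fs_batch <- function(data, method = c("auto", "exact", "asymptotic"),
                     diagnostics = FALSE, exact_max_n = 50L) {
  method <- match.arg(method)
  if (!all(c("n", "m", "theta") %in% names(data))) {
    stop("fs_batch(): data must have columns n, m, theta", call. = FALSE)
  }
  res <- purrr::pmap(list(data$n, data$m, data$theta), function(n, m, theta) {
    r <- fu_fs(n, m, theta, method = method, exact_max_n = exact_max_n)
    out <- tidy(r)[, c("s_prime", "t_prime", "fs", "branch", "method")]
    if (diagnostics) {
      g <- glance(r)
      out <- dplyr::bind_cols(out, g[, c("z0", "tau", "main_term",
                                         "correction", "fallback_used")])
    }
    out
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(res))
}
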