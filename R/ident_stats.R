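# Identification success rates and their Bernoulli (Wald) confidence
# intervals. Successes over independent queries are modelled as
# Bernoulli trials; the normal-approximation interval
# p +/- z * sqrt(p(1-p)/n) is reported, clipped to [0, 1].

#' Species-identification success rate
#'
#' The proportion of query sequences assigned to their correct
#' species. Stored as an exact ratio; rounding happens only at
#' printing (percentages to two decimals).
#'
#' @param hits Number of correctly assigned queries.
#' @param tests Total number of queries (>= 1).
#' @return A list of class `identification_result` with `hits`,
#'   `tests`, `rate` (exact proportion) and `rate_pct`.
#' @examples
#' success_rate(79, 80)$rate_pct # 98.75
#' @export
success_rate <- function(hits, tests) {
  if (length(tests) != 1L || tests < 1L) stop("tests must be >= 1")
  if (hits < 0L || hits > tests) stop("hits must be in [0, tests]")
  structure(
    list(
      hits = as.integer(hits), tests = as.integer(tests),
      rate = hits / tests, rate_pct = 100 * hits / tests
    ),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "Identification success: %d/%d (%.2f%%)\n", x$hits, x$tests, x$rate_pct
  ))
  invisible(x)
}

#' Wald confidence interval for a Bernoulli proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)` with
#' `z = qnorm(1 - alpha/2)`, clipped to the unit interval. The
#' critical value is computed from the normal quantile function, so
#' any level works. Note the well-known undercoverage of the Wald
#' interval near the boundaries (the interval degenerates to a point
#' at `p_hat` 0 or 1).
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Number of trials (>= 1).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A list of class `bernoulli_ci` with `p_hat`, `n`, `alpha`,
#'   `z`, `lower`, `upper`.
#' @examples
#' bernoulli_ci(0.5, 100) # roughly (0.402, 0.598)
#' @export
bernoulli_ci <- function(p_hat, n, alpha = 0.05) {
  if (n < 1L) stop("n must be >= 1")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  structure(
    list(
      p_hat = p_hat, n = as.integer(n), alpha = alpha, z = z,
      lower = max(0, p_hat - half), upper = min(1, p_hat + half)
    ),
    class = "bernoulli_ci"
  )
}

#' @export
print.bernoulli_ci <- function(x, ...) {
  cat(sprintf(
    "%.0f%% CI for proportion %.4f (n = %d): [%.4f, %.4f]\n",
    100 * (1 - x$alpha), x$p_hat, x$n, x$lower, x$upper
  ))
  invisible(x)
}

#' Success rate with its confidence interval, as a report block
#'
#' Convenience wrapper combining [success_rate()] and
#' [bernoulli_ci()] into the JSON-ready block used by the comparative
#' report.
#'
#' @param method Label for the identification method.
#' @param hits,tests Counts as in [success_rate()].
#' @param alpha Significance level for the interval.
#' @return A list with `method`, `hits`, `tests`, `rate_pct`,
#'   `ci_lower`, `ci_upper`, `alpha` (CI bounds on the percentage
#'   scale).
#' @export
rate_report <- function(method, hits, tests, alpha = 0.05) {
  sr <- success_rate(hits, tests)
  ci <- bernoulli_ci(sr$rate, tests, alpha)
  list(
    method = method, hits = sr$hits, tests = sr$tests,
    rate_pct = sr$rate_pct,
    ci_lower = 100 * ci$lower, ci_upper = 100 * ci$upper,
    alpha = alpha
  )
}
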