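# Exact two-sample t-test power and sample size on the non-central t
# distribution. With n1 (= n2) per group, common SD sigma and a true mean
# difference delta, the t statistic follows a non-central t with
# df = n1 + n2 - 2 and noncentrality ncp = delta / (sigma * sqrt(1/n1 + 1/n2));
# power is the probability that |T'| exceeds the two-sided critical value.

#' Power of the two-sided two-sample t test
#'
#' @param n_per_group per-group sample size (>= 2; may be non-integer for
#'   the continuous inversion used by [required_n()]).
#' @param delta true mean difference (same units as `sd`).
#' @param sd common standard deviation (> 0).
#' @param alpha two-sided significance level.
#' @param n2 second group size for unequal allocation (defaults to
#'   `n_per_group`).
#' @return power in (0, 1); vectorised over `n_per_group`.
#' @export
t_power <- function(n_per_group, delta, sd, alpha = 0.05, n2 = NULL) {
  if (!is.numeric(sd) || sd <= 0) abort("sd must be positive")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (any(n_per_group < 2)) abort("n_per_group must be >= 2")
  n2 <- if (is.null(n2)) n_per_group else n2
  if (any(n2 < 2)) abort("n2 must be >= 2")
  df <- n_per_group + n2 - 2
  ncp <- abs(delta) / (sd * sqrt(1 / n_per_group + 1 / n2))
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + (1 - pt(tcrit, df, ncp))
}

#' Per-group sample size for a target power
#'
#' Inverts the non-central-t power function. The continuous solution
#' `n*` (at which power exactly meets the target, treating `n` and the
#' degrees of freedom as continuous, as sample-size software reports it) is
#' found by root bisection; `rounding` then maps it to whole patients:
#'
#' * `"nearest"` (default): the nearest integer to `n*` — the convention of
#'   the clinical sample-size calculators this package mirrors; the achieved
#'   power at that n may sit marginally below the target (it is returned, so
#'   the trade-off is visible).
#' * `"up"`: the smallest integer n whose power meets or exceeds the target.
#'
#' @param delta true mean difference (nonzero).
#' @param sd common standard deviation.
#' @param alpha two-sided level.
#' @param power target power in (0, 1).
#' @param rounding `"nearest"` or `"up"` (see above).
#' @param max_n search cap; an unreachable target errors with the cap stated.
#' @return one-row tibble: `n` (per group), `power` (achieved at `n`),
#'   `n_continuous`, `ncp`, `df`.
#' @export
required_n <- function(delta, sd, alpha = 0.05, power = 0.8,
                       rounding = c("nearest", "up"), max_n = 1e6) {
  rounding <- match.arg(rounding)
  if (!is.numeric(delta) || delta == 0) abort("delta must be nonzero to solve for n")
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  if (t_power(max_n, delta, sd, alpha) < power) {
    abort(sprintf("target power %.6f unreachable within cap n = %g per group", power, max_n))
  }
  n_star <- if (t_power(2, delta, sd, alpha) >= power) {
    2
  } else {
    uniroot(function(n) t_power(n, delta, sd, alpha) - power,
            lower = 2, upper = max_n, tol = 1e-9)$root
  }
  n <- switch(rounding,
    nearest = max(2L, as.integer(round(n_star))),
    up = {
      cand <- max(2L, as.integer(floor(n_star)))
      while (t_power(cand, delta, sd, alpha) < power) cand <- cand + 1L
      cand
    }
  )
  achieved <- t_power(n, delta, sd, alpha)
  tibble::tibble(
    n = n, power = achieved, n_continuous = n_star,
    ncp = abs(delta) / (sd * sqrt(2 / n)), df = 2 * n - 2
  )
}
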