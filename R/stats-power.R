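#' Power of a paired t-test from the noncentral t distribution
#'
#' @param n Number of pairs.
#' @param d Standardized paired effect size (dz).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2.
#' @return Power (probability of rejecting H0).
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    q <- stats::qt(1 - alpha / 2, df)
    suppressWarnings(stats::pt(-q, df, ncp) + stats::pt(q, df, ncp,
                                                        lower.tail = FALSE))
  } else {
    q <- stats::qt(1 - alpha, df)
    suppressWarnings(stats::pt(q, df, ncp, lower.tail = FALSE))
  }
}

#' Sample size for a paired t-test
#'
#' Solves the continuous noncentral-t power equation for n (the same
#' computation `stats::power.t.test(type = "paired")` performs) and
#' reports an integer sample size. Sample-size recommendations in the
#' study-planning literature conventionally round the continuous
#' solution to the nearest integer, which is the default here;
#' `rounding = "ceiling"` instead returns the smallest integer n whose
#' power actually reaches the target.
#'
#' @param d Standardized paired effect size (> 0).
#' @param power Target power.
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @param rounding `"nearest"` (convention used when quoting planned
#'   sample sizes) or `"ceiling"` (guaranteed power).
#' @return Integer sample size; the continuous solution is attached as
#'   attribute `"n_continuous"`.
#' @examples
#' solve_power_paired_t(0.93, 0.99)  # 23
#' solve_power_paired_t(0.65, 0.95)  # 33
#' @export
solve_power_paired_t <- function(d, power, alpha = 0.05, tails = 2,
                                 rounding = c("nearest", "ceiling")) {
  stopifnot(d > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  rounding <- match.arg(rounding)
  f <- function(n) power_paired_t(n, d, alpha, tails) - power
  hi <- 4
  while (f(hi) < 0) hi <- hi * 2
  n_cont <- stats::uniroot(f, c(2, hi), tol = 1e-8)$root
  n <- if (rounding == "nearest") round(n_cont) else ceiling(n_cont - 1e-9)
  structure(as.integer(n), n_continuous = n_cont)
}

#' Power and sample size for a Pearson correlation
#'
#' `power_correlation()` computes the approximate power of a test of
#' H0: rho = 0. Two approximations are exposed: `"t_fisher"` transforms
#' the critical correlation (from the t distribution of r under H0) and
#' the bias-corrected population value to Fisher-z scale -- the
#' computation behind the widely used `pwr::pwr.r.test` -- and
#' `"fisher"` is the plain Fisher-z normal approximation. The two can
#' disagree by one participant at large effects; `"t_fisher"` is the
#' default because it reproduces the sample sizes quoted from `pwr`.
#'
#' @param n Sample size.
#' @param r Population correlation under H1 (0 < r < 1).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @param method `"t_fisher"` or `"fisher"`.
#' @return Power.
#' @export
power_correlation <- function(n, r, alpha = 0.05, tails = 1,
                              method = c("t_fisher", "fisher")) {
  method <- match.arg(method)
  stopifnot(n >= 4, r > 0, r < 1, tails %in% c(1, 2))
  a <- alpha / tails
  if (method == "t_fisher") {
    df <- n - 2
    ttt <- stats::qt(a, df, lower.tail = FALSE)
    rc <- sqrt(ttt^2 / (ttt^2 + df))
    zr <- atanh(r) + r / (2 * (n - 1))
    stats::pnorm((zr - atanh(rc)) * sqrt(n - 3))
  } else {
    stats::pnorm(atanh(r) * sqrt(n - 3) - stats::qnorm(1 - a))
  }
}

#' @rdname power_correlation
#' @param power Target power.
#' @return `solve_power_correlation()`: smallest integer n with power at
#'   least `power` under the chosen approximation.
#' @examples
#' solve_power_correlation(0.81, 0.95)  # 11 (t_fisher), 12 under "fisher"
#' @export
solve_power_correlation <- function(r, power, alpha = 0.05, tails = 1,
                                    method = c("t_fisher", "fisher")) {
  method <- match.arg(method)
  n <- 4L
  while (power_correlation(n, r, alpha, tails, method) < power) {
    n <- n + 1L
    if (n > 1e6) rlang::abort("no solution below n = 1e6.")
  }
  n
}
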