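#' Paired t-test with standardized effect size and CI of the mean
#' difference
#'
#' Classical paired t-test on `x - y` with Cohen's dz (mean difference
#' divided by the s.d. of differences, identically t/sqrt(n)) and the
#' confidence interval of the mean paired difference (CI_PD). One-tailed
#' tests report a one-sided interval with a single finite bound, e.g.
#' `[L, Inf)` for `tail = "upper"`.
#'
#' @param x,y Paired numeric vectors (participant means); `y = NULL`
#'   treats `x` as precomputed differences.
#' @param tail `"two"`, `"lower"` (H1: mean difference < 0) or
#'   `"upper"` (H1: mean difference > 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `kf_ttest`: `statistic`, `df`, `p`,
#'   `mean_diff`, `dz`, `ci` (length 2), `n`, `tail`, `zero_variance`.
#' @export
paired_t <- function(x, y = NULL, tail = c("two", "lower", "upper"),
                     conf_level = 0.95) {
  tail <- match.arg(tail)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) rlang::abort("paired test needs at least two pairs.")
  m <- mean(d); s <- stats::sd(d); df <- n - 1
  zero_var <- s == 0
  if (zero_var) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
    dz <- if (m == 0) 0 else sign(m) * Inf
  } else {
    se <- s / sqrt(n)
    t_stat <- m / se
    dz <- m / s
    p <- switch(tail,
      two = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
      lower = stats::pt(t_stat, df),
      upper = stats::pt(t_stat, df, lower.tail = FALSE))
    ci <- switch(tail,
      two = m + stats::qt(c((1 - conf_level) / 2,
                            1 - (1 - conf_level) / 2), df) * se,
      lower = c(-Inf, m + stats::qt(conf_level, df) * se),
      upper = c(m - stats::qt(conf_level, df) * se, Inf))
  }
  structure(list(statistic = t_stat, df = df, p = p, mean_diff = m,
                 dz = dz, ci = ci, n = n, tail = tail,
                 conf_level = conf_level, zero_variance = zero_var),
            class = "kf_ttest")
}

#' @export
print.kf_ttest <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.2f, p = %.4g, dz = %.2f, diff = %.3g, %g%% CI = [%.3g, %.3g]%s\n",
              x$df, x$statistic, x$p, x$dz, x$mean_diff,
              100 * x$conf_level, x$ci[1], x$ci[2],
              if (x$zero_variance) " (zero variance)" else ""))
  invisible(x)
}

#' Rank-based n-tiles
#'
#' Assigns each value to one of `k` near-equal-sized bins by rank; tied
#' values share the lower bin. With no ties, bin sizes differ by at most
#' one. Used here to form RT quartiles within participant and accuracy
#' condition.
#'
#' @param x Numeric vector.
#' @param k Number of bins (default 4).
#' @return Integer bin labels in `1:k`.
#' @export
ntiles <- function(x, k = 4) {
  x <- as.numeric(x)
  n <- sum(!is.na(x))
  if (n < k) rlang::abort("fewer values than bins.")
  r <- rank(x, ties.method = "min", na.last = "keep")
  as.integer(floor((r - 1) * k / n) + 1L)
}

#' Pearson correlation with t statistic
#'
#' @param x,y Numeric vectors.
#' @param tail `"two"`, `"lower"` (H1: r < 0) or `"upper"` (H1: r > 0).
#' @return Object of class `kf_cortest`: `r`, `statistic`, `df`, `p`,
#'   `n`, `tail`.
#' @export
pearson_correlation <- function(x, y, tail = c("two", "lower", "upper")) {
  tail <- match.arg(tail)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("correlation needs at least three pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: a variable has zero variance.")
  }
  r <- stats::cor(x, y)
  df <- n - 2
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- switch(tail,
    two = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
    lower = stats::pt(t_stat, df),
    upper = stats::pt(t_stat, df, lower.tail = FALSE))
  structure(list(r = r, statistic = t_stat, df = df, p = p, n = n,
                 tail = tail), class = "kf_cortest")
}

#' @export
print.kf_cortest <- function(x, ...) {
  cat(sprintf("r(%d) = %.2f, t(%d) = %.2f, p = %.4g (%s-tailed)\n",
              x$n, x$r, x$df, x$statistic, x$p,
              if (x$tail == "two") "two" else "one"))
  invisible(x)
}

#' Noncentral-t confidence interval for a paired standardized effect
#'
#' Inverts the noncentral t distribution: the bounds are the
#' noncentrality parameters (divided by sqrt(n)) for which the observed
#' t = dz*sqrt(n) sits at the (1 +/- level)/2 tail probabilities.
#'
#' @param dz Observed standardized paired mean difference.
#' @param n Number of pairs.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric interval for the population effect size.
#' @examples
#' ci_dz(1.34, 44)  # about [0.93, 1.74]
#' @export
ci_dz <- function(dz, n, level = 0.95) {
  stopifnot(n >= 2, level > 0, level < 1)
  t_obs <- dz * sqrt(n)
  df <- n - 1
  bound <- function(prob) {
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - prob
    lo <- t_obs - 10 * sqrt(1 + t_obs^2); hi <- t_obs + 10 * sqrt(1 + t_obs^2)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  c(bound((1 + level) / 2), bound((1 - level) / 2)) / sqrt(n)
}
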