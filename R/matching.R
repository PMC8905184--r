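#' Greedy matching of error trials to correct trials
#'
#' Within each participant, error trials are visited from the lowest to
#' the highest trial number; each is paired with the still-unmatched
#' correct trial minimising the absolute difference in the match
#' variable (RT or PF). Ties are broken by the smallest absolute
#' trial-number distance to the error trial, then by the smaller trial
#' number. Every matched correct trial becomes unavailable, so the
#' pairing is injective and order-dependent by design -- fidelity to the
#' registered procedure, not global optimality, is the point.
#'
#' @param selected Classified, selected feature rows (needs `outcome`,
#'   `trial_global`, `participant_id` and the match variable).
#' @param variable `"rt"` or `"pf"`.
#' @return Tibble of class `kf_match`: `participant_id`, `error_trial`,
#'   `correct_trial`, `error_value`, `correct_value`, `delta`
#'   (correct minus error). Errors if any participant has more error
#'   than correct trials.
#' @export
greedy_match <- function(selected, variable = c("rt", "pf")) {
  variable <- match.arg(variable)
  parts <- split(selected, selected$participant_id)
  res <- lapply(parts, function(d) {
    err <- d[d$outcome == "commission", ]
    cor <- d[d$outcome == "correct", ]
    if (nrow(err) > nrow(cor)) {
      rlang::abort(sprintf(
        "participant %s: %d error but only %d correct trials; matching cannot complete.",
        d$participant_id[1], nrow(err), nrow(cor)))
    }
    err <- err[order(err$trial_global), ]
    ev <- err[[variable]]; cv <- cor[[variable]]
    et <- err$trial_global; ct <- cor$trial_global
    free <- rep(TRUE, nrow(cor))
    pick <- integer(nrow(err))
    for (i in seq_len(nrow(err))) {
      cand <- which(free)
      dv <- abs(cv[cand] - ev[i])
      cand <- cand[dv == min(dv)]
      if (length(cand) > 1) {
        dtrial <- abs(ct[cand] - et[i])
        cand <- cand[dtrial == min(dtrial)]
      }
      if (length(cand) > 1) cand <- cand[which.min(ct[cand])]
      pick[i] <- cand
      free[cand] <- FALSE
    }
    tibble::tibble(
      participant_id = err$participant_id,
      error_trial = et, correct_trial = ct[pick],
      error_value = ev, correct_value = cv[pick],
      delta = cv[pick] - ev
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("kf_match", class(out))
  attr(out, "variable") <- variable
  out
}

#' TOST equivalence test on matched differences
#'
#' Participant-level mean differences (correct minus error) are tested
#' against symmetric bounds in two one-tailed one-sample t-tests:
#' greater than `-bound` and less than `+bound`. Equivalence is claimed
#' only when both tests are significant at `alpha`; the reported
#' statistic is the one with the smaller absolute t. Participants whose
#' mean difference is at or beyond a bound are listed as offenders for
#' the trimming loop. Zero variance across participants yields an
#' infinite t and an automatic (flagged) pass.
#'
#' @param match A `kf_match` tibble from [greedy_match()], or a tibble
#'   with `participant_id` and `delta`.
#' @param bound Equivalence bound (2 ms for RT, 0.05 a.u. for PF).
#' @param alpha One-tailed significance level per test (default 0.05).
#' @return List of class `kf_equivalence`: per-participant means,
#'   `t_lower`, `t_upper`, `df`, `p_lower`, `p_upper`, the reported
#'   test, `pass`, `offenders`, `zero_variance`.
#' @export
equivalence_test <- function(match, bound, alpha = 0.05) {
  stopifnot(bound > 0)
  means <- match |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_delta = mean(.data$delta), .groups = "drop")
  m <- means$mean_delta
  n <- length(m)
  if (n < 2) rlang::abort("equivalence testing needs at least two participants.")
  s <- stats::sd(m)
  df <- n - 1
  zero_var <- s == 0
  if (zero_var) {
    # degenerate t; signs (and exact-boundary zeros) keep the decision
    # logic of the finite case: inside both bounds -> flagged auto-pass
    mu <- mean(m)
    t_lower <- if (mu > -bound) Inf else if (mu == -bound) 0 else -Inf
    t_upper <- if (mu < bound) -Inf else if (mu == bound) 0 else Inf
    p_lower <- if (mu > -bound) 0 else if (mu == -bound) 0.5 else 1
    p_upper <- if (mu < bound) 0 else if (mu == bound) 0.5 else 1
  } else {
    se <- s / sqrt(n)
    t_lower <- (mean(m) + bound) / se   # H1: mean > -bound
    t_upper <- (mean(m) - bound) / se   # H1: mean < +bound
    p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
    p_upper <- stats::pt(t_upper, df)
  }
  pass <- p_lower < alpha && p_upper < alpha
  reported <- if (abs(t_lower) <= abs(t_upper)) "lower" else "upper"
  offenders <- means$participant_id[m <= -bound | m >= bound]
  structure(list(
    means = means, bound = bound, alpha = alpha, df = df,
    t_lower = t_lower, t_upper = t_upper,
    p_lower = p_lower, p_upper = p_upper,
    reported = reported,
    t_reported = if (reported == "lower") t_lower else t_upper,
    p_reported = if (reported == "lower") p_lower else p_upper,
    pass = pass, offenders = offenders, zero_variance = zero_var
  ), class = "kf_equivalence")
}

#' @export
print.kf_equivalence <- function(x, ...) {
  cat(sprintf(
    "TOST vs +/-%g: t_lower(%d) = %.2f (p = %.4f), t_upper = %.2f (p = %.4f) -> %s\n",
    x$bound, x$df, x$t_lower, x$p_lower, x$t_upper, x$p_upper,
    if (x$pass) "equivalent" else "not equivalent"))
  if (length(x$offenders)) {
    cat("offenders:", paste(x$offenders, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Iterative trim-and-rematch loop
#'
#' Matches error to correct trials, checks equivalence, and -- while the
#' TOST fails -- trims error trials and re-matches: if any participant's
#' mean difference sits at or beyond a bound (offender), the bottom 5%
#' of *that participant's* error trials (smallest values of the match
#' variable, at least one trial) are removed; otherwise the bottom 5%
#' is trimmed for all participants. Trims accumulate across iterations.
#' The loop stops on a passing TOST, after `max_iter` iterations, or
#' when a further trim would push a participant below `min_obs` error
#' trials (that participant is flagged for upstream exclusion).
#'
#' @inheritParams greedy_match
#' @inheritParams equivalence_test
#' @param trim Fraction of error trials removed per trim (default 0.05).
#' @param max_iter Maximum number of match-trim cycles (default 20).
#' @param min_obs Minimum error trials a participant must keep.
#' @return List of class `kf_matchloop`: final `match`, `equivalence`,
#'   `iterations`, per-iteration `log`, ids of `trimmed` error trials,
#'   `flagged` participants, and `converged`.
#' @export
trim_and_rematch <- function(selected, variable = c("rt", "pf"), bound,
                             alpha = 0.05, trim = 0.05, max_iter = 20,
                             min_obs = 10) {
  variable <- match.arg(variable)
  if (missing(bound)) bound <- if (variable == "rt") 2 else 0.05
  data <- selected
  trimmed <- integer(0)
  log <- list()
  flagged <- integer(0)
  iter <- 0
  repeat {
    match <- greedy_match(data, variable)
    eq <- equivalence_test(match, bound, alpha)
    log[[length(log) + 1]] <- tibble::tibble(
      iteration = iter, n_pairs = nrow(match),
      t_lower = eq$t_lower, t_upper = eq$t_upper, pass = eq$pass,
      n_offenders = length(eq$offenders))
    if (eq$pass || iter >= max_iter) break

    who <- if (length(eq$offenders)) eq$offenders else
      unique(data$participant_id[data$outcome == "commission"])
    n_dropped <- 0L
    blocked <- FALSE
    for (p in who) {
      errs <- data[data$participant_id == p & data$outcome == "commission", ]
      n_drop <- max(1L, ceiling(trim * nrow(errs)))
      if (nrow(errs) - n_drop < min_obs) {
        flagged <- union(flagged, p)
        blocked <- TRUE
        next
      }
      ord <- order(errs[[variable]], errs$trial_global)
      ids <- errs$trial_global[ord[seq_len(n_drop)]]
      data <- data[!(data$participant_id == p &
                       data$trial_global %in% ids &
                       data$outcome == "commission"), ]
      trimmed <- c(trimmed, ids)
      n_dropped <- n_dropped + n_drop
    }
    if (blocked && n_dropped == 0L) break
    iter <- iter + 1
  }
  structure(list(match = match, equivalence = eq, iterations = iter,
                 log = dplyr::bind_rows(log), trimmed = trimmed,
                 flagged = flagged, converged = eq$pass,
                 variable = variable, bound = bound),
            class = "kf_matchloop")
}

#' @export
print.kf_matchloop <- function(x, ...) {
  cat(sprintf("trim-and-rematch on %s (bound %g): %s after %d iteration(s), %d pairs\n",
              toupper(x$variable), x$bound,
              if (x$converged) "equivalence reached" else "no equivalence",
              x$iterations, nrow(x$match)))
  if (length(x$flagged))
    cat("flagged for upstream exclusion:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
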