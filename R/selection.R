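#' Classify trial outcomes
#'
#' Joins extracted features with trial metadata and assigns exactly one
#' outcome class per trial: `anticipatory` if the response threshold was
#' crossed during fixation (onset before target onset), `omission` if no
#' supra-threshold response occurred anywhere in the trial, `commission`
#' if the responding key differs from the assigned key, `correct`
#' otherwise. A `miscellaneous` level exists for keyboard-format pilot
#' data (wrong keys or multiple presses), which cannot occur with two
#' force keys.
#'
#' @param features Feature tibble from [extract_features()].
#' @param trials Trial metadata with `participant_id`, `trial_global`,
#'   `is_practice` and `correct_key`.
#' @return `features` joined with metadata plus an `outcome` column.
#' @export
classify_outcomes <- function(features, trials) {
  meta_cols <- intersect(
    c("participant_id", "trial_global", "is_practice", "correct_key",
      "target_letter"), names(trials))
  out <- dplyr::left_join(features, trials[, meta_cols],
                          by = c("participant_id", "trial_global"))
  out$outcome <- factor(dplyr::case_when(
    !out$supra_threshold ~ "omission",
    out$onset_time < 0 ~ "anticipatory",
    out$response_key != out$correct_key ~ "commission",
    TRUE ~ "correct"
  ), levels = c("correct", "commission", "omission", "anticipatory",
                "miscellaneous"))
  out
}

#' Apply the trial-level exclusion cascade
#'
#' In order: drop the practice block; drop the first trial of every
#' block; keep only trials whose immediately preceding trial (in the
#' original chronology, before any removal) had a correct outcome; drop
#' anticipatory, omission and miscellaneous trials, leaving correct
#' responses and commission errors. The function is idempotent, and a
#' per-stage audit log is attached as the `"selection_log"` attribute
#' (retrievable with [selection_log()]).
#'
#' @param classified Output of [classify_outcomes()], chronologically
#'   ordered within participants (checked).
#' @return The surviving trials, with the log attached.
#' @export
apply_filters <- function(classified) {
  d <- classified
  ord <- unlist(lapply(split(d$trial_global, d$participant_id),
                       function(x) !is.unsorted(x, strictly = TRUE)),
                use.names = FALSE)
  if (!all(ord)) rlang::abort("trials must be in chronological order within participants.")

  log <- list()
  n0 <- nrow(d)
  # the verdict about the preceding trial refers to the original
  # chronology; it is stored so that re-applying the cascade to an
  # already-filtered table cannot re-evaluate it against survivors only
  if ("prev_correct" %in% names(d)) {
    prev_correct <- d$prev_correct
  } else {
    prev_correct <- dplyr::lag(d$outcome == "correct", default = FALSE) &
      dplyr::lag(d$participant_id, default = -1L) == d$participant_id
    d$prev_correct <- prev_correct
  }

  keep1 <- if ("is_practice" %in% names(d)) !d$is_practice else rep(TRUE, nrow(d))
  log$practice <- sum(!keep1)
  keep2 <- keep1 & d$trial_in_block != 1L
  log$first_of_block <- sum(keep1 & !keep2)
  keep3 <- keep2 & prev_correct
  log$preceding_not_correct <- sum(keep2 & !keep3)
  keep4 <- keep3 & d$outcome %in% c("correct", "commission")
  log$other_outcome <- sum(keep3 & !keep4)
  out <- d[keep4, ]
  log <- tibble::tibble(
    stage = c("input", names(log), "selected"),
    removed = c(0L, unlist(log, use.names = FALSE), 0L),
    remaining = c(n0, n0 - cumsum(unlist(log, use.names = FALSE)), nrow(out))
  )
  attr(out, "selection_log") <- log
  out
}

#' @rdname apply_filters
#' @param selected A tibble returned by [apply_filters()] or
#'   [select_trials()].
#' @export
selection_log <- function(selected) attr(selected, "selection_log")

#' Remove outlier trials within participant-by-accuracy cells
#'
#' Single, non-iterative pass: per participant x outcome cell, a trial
#' is removed when its RT, RD or PF lies more than `k` standard
#' deviations from the cell mean of that variable (means and s.d.s
#' computed on the input set). Cells with fewer than two trials are left
#' untouched (the s.d. is undefined). Removal is invariant to trial
#' order.
#'
#' @param selected Output of [apply_filters()].
#' @param k Deviation criterion in standard deviations (default 2.5).
#' @param vars Feature columns screened (default RT, RD, PF).
#' @return The surviving trials; removed fraction in attribute
#'   `"outlier_fraction"`.
#' @export
filter_outliers <- function(selected, k = 2.5, vars = c("rt", "rd", "pf")) {
  d <- selected |>
    dplyr::group_by(.data$participant_id, .data$outcome)
  flag <- rep(FALSE, nrow(selected))
  for (v in vars) {
    z <- d |>
      dplyr::mutate(.out = {
        n <- sum(!is.na(.data[[v]]))
        if (n < 2) rep(FALSE, dplyr::n())
        else abs(.data[[v]] - mean(.data[[v]])) > k * stats::sd(.data[[v]])
      }) |>
      dplyr::pull(".out")
    flag <- flag | (z %in% TRUE)
  }
  out <- dplyr::ungroup(d)[!flag, ]
  attr(out, "selection_log") <- attr(selected, "selection_log")
  attr(out, "outlier_fraction") <- mean(flag)
  out
}

#' Participant-level quality gates
#'
#' A participant is excluded when they responded correctly in less than
#' `min_correct_pct` percent of the experimental trials (percentage base:
#' all non-practice, non-first-of-block trials, before the
#' preceding-trial filter), or when fewer than `min_cell` trials remain
#' in either accuracy cell after the full trial-level cascade. Both
#' thresholds are strict (`<`): a participant at exactly 60% or exactly
#' 10 observations is retained.
#'
#' @param classified Output of [classify_outcomes()] (all trials).
#' @param selected Trials surviving [apply_filters()] and
#'   [filter_outliers()].
#' @param min_correct_pct Minimum percentage of correct responses.
#' @param min_cell Minimum trials per accuracy cell.
#' @return Tibble: `participant_id`, `pct_correct`, `n_correct`,
#'   `n_commission`, `include`, `reason` (`NA` when included).
#' @export
participant_gates <- function(classified, selected, min_correct_pct = 60,
                              min_cell = 10) {
  base <- classified
  if ("is_practice" %in% names(base)) base <- base[!base$is_practice, ]
  base <- base[base$trial_in_block != 1L, ]
  acc <- base |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(pct_correct = 100 * mean(.data$outcome == "correct"),
                     .groups = "drop")
  cells <- selected |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_correct = sum(.data$outcome == "correct"),
                     n_commission = sum(.data$outcome == "commission"),
                     .groups = "drop")
  out <- dplyr::left_join(acc, cells, by = "participant_id") |>
    dplyr::mutate(n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  n_commission = dplyr::coalesce(.data$n_commission, 0L))
  out$reason <- dplyr::case_when(
    out$pct_correct < min_correct_pct ~ "accuracy_below_minimum",
    pmin(out$n_correct, out$n_commission) < min_cell ~ "cell_below_minimum",
    TRUE ~ NA_character_
  )
  out$include <- is.na(out$reason)
  out
}

#' Full trial-selection cascade
#'
#' Convenience wrapper: classify outcomes, apply the trial filters,
#' remove outliers, gate participants, and return the analysable trial
#' set restricted to included participants. The per-stage log and the
#' gate table travel as attributes.
#'
#' @inheritParams classify_outcomes
#' @inheritParams filter_outliers
#' @inheritParams participant_gates
#' @return Selected feature rows of included participants, with
#'   attributes `"selection_log"`, `"gates"` and `"outlier_fraction"`.
#' @export
select_trials <- function(features, trials, k = 2.5, min_correct_pct = 60,
                          min_cell = 10) {
  cl <- classify_outcomes(features, trials)
  sel <- apply_filters(cl)
  sel <- filter_outliers(sel, k = k)
  gates <- participant_gates(cl, sel, min_correct_pct, min_cell)
  out <- sel[sel$participant_id %in% gates$participant_id[gates$include], ]
  attr(out, "selection_log") <- attr(sel, "selection_log")
  attr(out, "outlier_fraction") <- attr(sel, "outlier_fraction")
  attr(out, "gates") <- gates
  out
}
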