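#' Analysis run configuration
#'
#' Bundles every tunable constant of the registered analysis chain so a
#' run can be reproduced from its echoed configuration: registration
#' and covert thresholds (a.u.), equivalence bounds (ms / a.u.),
#' outlier criterion, significance level, gate thresholds, matching
#' loop controls, and the open-question switches.
#'
#' @param response_threshold Registration threshold, a.u.
#' @param covert_threshold Low threshold for covert responses, a.u.
#' @param rt_bound RT equivalence bound, ms.
#' @param pf_bound PF equivalence bound, a.u.
#' @param outlier_k Outlier criterion in cell standard deviations.
#' @param alpha Significance level for all frequentist tests.
#' @param min_correct_pct Participant gate: minimum percent correct.
#' @param min_cell Participant gate: minimum trials per accuracy cell.
#' @param max_iter Maximum trim-and-rematch iterations.
#' @param trim Fraction of error trials trimmed per iteration.
#' @param cauchy_scale Prior scale of the fallback JZS t-tests.
#' @param cor_prior_width Stretched-beta width of the fallback
#'   correlation Bayes factor.
#' @return List of class `kf_run_config`.
#' @export
run_config <- function(response_threshold = 0.25, covert_threshold = 0.1,
                       rt_bound = 2, pf_bound = 0.05, outlier_k = 2.5,
                       alpha = 0.05, min_correct_pct = 60, min_cell = 10,
                       max_iter = 20, trim = 0.05, cauchy_scale = 1,
                       cor_prior_width = 1 / 3) {
  cfg <- as.list(environment())
  stopifnot(response_threshold > 0, covert_threshold > 0,
            rt_bound > 0, pf_bound > 0, outlier_k > 0,
            alpha > 0, alpha < 1)
  structure(cfg, class = "kf_run_config")
}

#' Per-participant difference in total area under the curve
#'
#' Overall summary statistic of the force-attenuation effect: the
#' summed pre- and post-peak AUCs of the unmatched data, correct minus
#' error, per participant.
#'
#' @param aucs Tibble with `participant_id`, `outcome`, `auc_pre`,
#'   `auc_post` (one row per cell, both accuracies present).
#' @return Tibble `participant_id`, `delta_auc`. Participants missing a
#'   condition are skipped (with a message).
#' @export
compute_delta_auc <- function(aucs) {
  tot <- aucs |>
    dplyr::mutate(total = .data$auc_pre + .data$auc_post) |>
    dplyr::select("participant_id", "outcome", "total") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "total")
  if (!all(c("correct", "commission") %in% names(tot))) {
    rlang::abort("need AUCs for both accuracy conditions.")
  }
  miss <- is.na(tot$correct) | is.na(tot$commission)
  if (any(miss)) {
    rlang::inform(sprintf("skipping %d participant(s) without both conditions.",
                          sum(miss)))
  }
  tibble::tibble(participant_id = tot$participant_id[!miss],
                 delta_auc = tot$correct[!miss] - tot$commission[!miss])
}

#' Percentage of correct trials with covert activity on the other key
#'
#' @param selected Selected, classified feature rows (unmatched data).
#' @return Tibble `participant_id`, `n_correct`, `covert_rate`
#'   (percent). Participants without correct trials are dropped with a
#'   message.
#' @export
covert_rate <- function(selected) {
  out <- selected |>
    dplyr::filter(.data$outcome == "correct") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_correct = dplyr::n(),
                     covert_rate = 100 * mean(.data$covert_other_key),
                     .groups = "drop")
  missing <- setdiff(unique(selected$participant_id), out$participant_id)
  if (length(missing)) {
    rlang::inform(sprintf(
      "participant(s) %s have no correct trials; excluded from the covert-rate analysis.",
      paste(missing, collapse = ", ")))
  }
  out
}

# participant x accuracy x window cell means of the pre-/post-peak RD
.rd_cells <- function(features) {
  features |>
    dplyr::group_by(.data$participant_id, .data$outcome) |>
    dplyr::summarise(pre = mean(.data$rd_pre_peak),
                     post = mean(.data$rd_post_peak), .groups = "drop") |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "window",
                        values_to = "rd") |>
    dplyr::mutate(window = factor(.data$window, levels = c("pre", "post")),
                  outcome = factor(.data$outcome,
                                   levels = c("correct", "commission")))
}

# one 2x2 accuracy x window analysis with conditional one-tailed follow-ups
.acc_window_analysis <- function(cells, dv, alpha) {
  an <- rm_anova(cells, dv, within = c("outcome", "window"))
  tab <- an$table
  int_p <- tab$p[tab$effect == "outcome:window"]
  wide <- tidyr::pivot_wider(cells, names_from = c("outcome", "window"),
                             values_from = dplyr::all_of(dv))
  follow <- NULL
  if (is.finite(int_p) && int_p < alpha) {
    follow <- list(
      pre = paired_t(wide$correct_pre, wide$commission_pre, tail = "upper"),
      post = paired_t(wide$correct_post, wide$commission_post, tail = "upper"))
  }
  acc_means <- cells |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(m = mean(.data[[dv]]), .groups = "drop")
  err_lower <- acc_means$m[acc_means$outcome == "commission"] <
    acc_means$m[acc_means$outcome == "correct"]
  list(anova = an, followups = follow, interaction_p = int_p,
       accuracy_p = tab$p[tab$effect == "outcome"],
       error_lower = err_lower, cells = cells)
}

.dataset_from_match <- function(selected, match, drop_participants) {
  ids <- c(paste(match$participant_id, match$error_trial),
           paste(match$participant_id, match$correct_trial))
  out <- selected[paste(selected$participant_id, selected$trial_global)
                  %in% ids, ]
  out[!out$participant_id %in% drop_participants, ]
}

#' Run the registered analysis pipeline end to end
#'
#' Selection cascade, matched-dataset construction with iterative
#' equivalence-driven trimming, and the full hypothesis chain: 2x2
#' accuracy-by-time-window ANOVAs on response durations (unmatched,
#' RT-matched, PF-matched) with conditional one-tailed follow-ups and a
#' Bayesian fallback; the same ANOVAs on areas under the peak-locked
#' relative force profiles; the gated 5x2 windowed-force ANOVA; the
#' correlation of the AUC difference with the covert-response rate
#' (with Bayesian fallback); and the one-tailed RT and PF validation
#' tests. Gate failures (participant counts, missing traces) are
#' surfaced in the report, never silent.
#'
#' @param forces Long force-sample tibble, or `NULL` to run the
#'   feature-only part of the chain (the AUC-based analyses need
#'   traces).
#' @param trials Trial metadata.
#' @param features Per-trial features; computed from `forces` when
#'   omitted.
#' @param config A [run_config()].
#' @return Object of class `kf_report`; see [decide_hypotheses()],
#'   [tidy.kf_report()] and [report_json()].
#' @export
run_pipeline <- function(forces = NULL, trials, features = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "kf_run_config"))
  if (is.null(features)) {
    if (is.null(forces)) rlang::abort("need `forces` or `features`.")
    features <- extract_features(forces,
                                 response_threshold = config$response_threshold,
                                 covert_threshold = config$covert_threshold)
  }
  notes <- character(0)

  selected <- select_trials(features, trials, k = config$outlier_k,
                            min_correct_pct = config$min_correct_pct,
                            min_cell = config$min_cell)
  gates <- attr(selected, "gates")
  n_inc <- length(unique(selected$participant_id))
  if (n_inc < 2) {
    rlang::abort(sprintf(
      "only %d participant(s) pass the quality gates (%d assessed); the registered analyses need at least two. Gate reasons: %s.",
      n_inc, nrow(gates),
      paste(stats::na.omit(unique(gates$reason)), collapse = ", ")))
  }

  loops <- list(
    rt = trim_and_rematch(selected, "rt", bound = config$rt_bound,
                          alpha = config$alpha, trim = config$trim,
                          max_iter = config$max_iter,
                          min_obs = config$min_cell),
    pf = trim_and_rematch(selected, "pf", bound = config$pf_bound,
                          alpha = config$alpha, trim = config$trim,
                          max_iter = config$max_iter,
                          min_obs = config$min_cell))
  flagged <- union(loops$rt$flagged, loops$pf$flagged)
  if (length(flagged)) {
    notes <- c(notes, sprintf(
      "participant(s) %s fell below %d error trials during trimming; excluded from all datasets.",
      paste(flagged, collapse = ", "), config$min_cell))
    selected <- selected[!selected$participant_id %in% flagged, ]
    loops$rt <- trim_and_rematch(selected, "rt", bound = config$rt_bound,
                                 alpha = config$alpha, trim = config$trim,
                                 max_iter = config$max_iter,
                                 min_obs = config$min_cell)
    loops$pf <- trim_and_rematch(selected, "pf", bound = config$pf_bound,
                                 alpha = config$alpha, trim = config$trim,
                                 max_iter = config$max_iter,
                                 min_obs = config$min_cell)
  }

  datasets <- list(
    unmatched = selected,
    rt_matched = .dataset_from_match(selected, loops$rt$match, flagged),
    pf_matched = .dataset_from_match(selected, loops$pf$match, flagged))

  alpha <- config$alpha
  rd <- lapply(datasets, function(d) .acc_window_analysis(.rd_cells(d), "rd", alpha))

  h1_all_sig <- all(vapply(rd, function(a)
    is.finite(a$accuracy_p) && a$accuracy_p < alpha && a$error_lower, TRUE))
  h1_bayes <- NULL
  if (!h1_all_sig) {
    h1_bayes <- lapply(datasets, function(d) {
      diffs <- .rd_diffs(d)
      list(bf = bayes_t_paired(diffs, cauchy_scale = config$cauchy_scale),
           trajectory = bf_trajectory(diffs, cauchy_scale = config$cauchy_scale))
    })
    notes <- c(notes, "H1 not significant in all datasets: Bayesian fallback reported; sequential rule evaluated on available participants only.")
  }

  auc <- NULL
  h5 <- list(ran = FALSE, reason = "gate_failed")
  h6 <- NULL
  if (!is.null(forces)) {
    profs <- .analysis_profiles(forces, datasets)
    auc <- lapply(names(datasets), function(ds) {
      prof <- profs$peak[profs$peak$dataset == ds, ]
      aucs <- prof |>
        dplyr::group_by(.data$participant_id, .data$outcome) |>
        dplyr::group_modify(~ profile_auc(.x)) |>
        dplyr::ungroup()
      cells <- aucs |>
        dplyr::select("participant_id", "outcome", "auc_pre", "auc_post") |>
        tidyr::pivot_longer(c("auc_pre", "auc_post"), names_to = "window",
                            values_to = "auc") |>
        dplyr::mutate(window = factor(sub("auc_", "", .data$window),
                                      levels = c("pre", "post")),
                      outcome = factor(.data$outcome,
                                       levels = c("correct", "commission")))
      res <- .acc_window_analysis(cells, "auc", alpha)
      res$aucs <- aucs
      res
    })
    names(auc) <- names(datasets)

    pre_sig <- vapply(auc, function(a) {
      !is.null(a$followups) && a$followups$pre$p < alpha
    }, TRUE)
    if (all(pre_sig)) {
      mrt <- mean(datasets$rt_matched$rt)
      prof_t <- profs$target
      wf <- prof_t |>
        dplyr::group_by(.data$participant_id, .data$outcome) |>
        dplyr::group_modify(~ windowed_mean_forces(
          dplyr::rename(.x, value = "value"), mrt)) |>
        dplyr::ungroup() |>
        dplyr::mutate(outcome = factor(.data$outcome,
                                       levels = c("correct", "commission")))
      an5 <- rm_anova(wf, "mean_force", within = c("window", "outcome"))
      int_p <- an5$table$p[an5$table$effect == "window:outcome"]
      fol5 <- NULL
      if (is.finite(int_p) && int_p < alpha) {
        fol5 <- lapply(split(wf, wf$window), function(d) {
          wide <- tidyr::pivot_wider(d, names_from = "outcome",
                                     values_from = "mean_force")
          paired_t(wide$correct, wide$commission, tail = "upper")
        })
      }
      h5 <- list(ran = TRUE, mean_matched_rt = mrt, anova = an5,
                 followups = fol5, cells = wf)
    } else {
      h5$reason <- "pre-peak AUC effect not significant in all three datasets"
    }

    dauc <- compute_delta_auc(auc$unmatched$aucs)
    crate <- covert_rate(datasets$unmatched)
    joint <- dplyr::inner_join(dauc, crate, by = "participant_id")
    cor_test <- pearson_correlation(joint$delta_auc, joint$covert_rate,
                                    tail = "upper")
    h6 <- list(delta_auc = dauc, covert = crate, test = cor_test,
               bayes = if (cor_test$p >= alpha)
                 bayes_correlation(cor_test$r, cor_test$n, tail = "upper",
                                   width = config$cor_prior_width))
  } else {
    notes <- c(notes, "no raw traces supplied: AUC-based analyses (overall-force and covert-link hypotheses) skipped.")
  }

  rtpf <- datasets$unmatched |>
    dplyr::group_by(.data$participant_id, .data$outcome) |>
    dplyr::summarise(rt = mean(.data$rt), pf = mean(.data$pf),
                     .groups = "drop")
  wide_rt <- tidyr::pivot_wider(rtpf[, c("participant_id", "outcome", "rt")],
                                names_from = "outcome", values_from = "rt")
  wide_pf <- tidyr::pivot_wider(rtpf[, c("participant_id", "outcome", "pf")],
                                names_from = "outcome", values_from = "pf")
  h7 <- paired_t(wide_rt$correct, wide_rt$commission, tail = "upper")
  h8 <- paired_t(wide_pf$correct, wide_pf$commission, tail = "upper")

  report <- structure(list(
    config = config, selection = list(log = selection_log(selected),
                                      gates = gates),
    matching = loops, datasets = datasets, rd = rd, auc = auc,
    h1_bayes = h1_bayes, h5 = h5, h6 = h6, h7 = h7, h8 = h8,
    notes = notes), class = "kf_report")
  report$decisions <- decide_hypotheses(report_summary(report))
  report
}

# participant-level RD differences (correct - commission), id order
.rd_diffs <- function(features) {
  w <- features |>
    dplyr::group_by(.data$participant_id, .data$outcome) |>
    dplyr::summarise(rd = mean(.data$rd), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "rd") |>
    dplyr::arrange(.data$participant_id)
  w$correct - w$commission
}

#' Compact logical summary of a pipeline report
#'
#' Reduces a `kf_report` to the branch conditions the registered
#' decision tree consumes; [decide_hypotheses()] maps this structure to
#' interpretation labels, so fabricated summaries can exercise every
#' branch.
#'
#' @param report A `kf_report`.
#' @return Nested list (`rd`, `auc`, `h5`, `h6`, `h7`, `h8`, `alpha`).
#' @export
report_summary <- function(report) {
  alpha <- report$config$alpha
  squash <- function(a) {
    if (is.null(a)) return(NULL)
    list(acc_sig = is.finite(a$accuracy_p) && a$accuracy_p < alpha &&
           a$error_lower,
         int_sig = is.finite(a$interaction_p) && a$interaction_p < alpha,
         pre_sig = !is.null(a$followups) && a$followups$pre$p < alpha,
         post_sig = !is.null(a$followups) && a$followups$post$p < alpha)
  }
  h1b <- if (!is.null(report$h1_bayes))
    vapply(report$h1_bayes, function(b) b$bf$bf01, 0)
  h5 <- report$h5
  list(
    rd = lapply(report$rd, squash),
    auc = if (!is.null(report$auc)) lapply(report$auc, squash),
    h1_bf01 = h1b,
    h5 = list(ran = isTRUE(h5$ran),
              main_sig = isTRUE(h5$ran) && {
                tab <- h5$anova$table
                tab$p[tab$effect == "outcome"] < alpha
              },
              int_sig = isTRUE(h5$ran) && {
                tab <- h5$anova$table
                tab$p[tab$effect == "window:outcome"] < alpha
              },
              window_sig = if (isTRUE(h5$ran) && !is.null(h5$followups))
                vapply(h5$followups, function(t) t$p < alpha, TRUE)),
    h6 = if (!is.null(report$h6))
      list(sig = report$h6$test$p < alpha,
           bf10 = if (!is.null(report$h6$bayes)) report$h6$bayes$bf10),
    h7 = list(sig = report$h7$p < alpha),
    h8 = list(sig = report$h8$p < alpha),
    alpha = alpha)
}

#' Map test outcomes to the registered interpretation labels
#'
#' Deterministic translation of the branch conditions (see
#' [report_summary()]) into the interpretation column of the study
#' design: active error cancellation requires shorter error durations
#' in all three datasets; mixed results trigger the Bayesian fallback;
#' early versus late cancellation and force attenuation follow the
#' conditional follow-up logic; the windowed analysis and the
#' covert-link correlation carry their own gates.
#'
#' @param s Summary list from [report_summary()] (or fabricated with
#'   the same shape).
#' @return Tibble: `hypothesis`, `decision`.
#' @export
decide_hypotheses <- function(s) {
  dec <- list()
  rd_all <- all(vapply(s$rd, `[[`, TRUE, "acc_sig"))
  if (rd_all) {
    dec$H1 <- "active_cancellation_inferred"
  } else if (!is.null(s$h1_bf01)) {
    if (all(s$h1_bf01 > 10)) dec$H1 <- "standard_model_supported"
    else if (all(s$h1_bf01 < 0.1)) dec$H1 <- "cancellation_supported_by_bayes"
    else dec$H1 <- "bayesian_fallback_continue_sampling"
  } else {
    dec$H1 <- "bayesian_fallback_triggered"
  }

  tree_h2 <- function(block) {
    ints <- vapply(block, `[[`, TRUE, "int_sig")
    if (!any(ints)) return("no_interaction_time_course_not_explored")
    pre <- vapply(block, `[[`, TRUE, "pre_sig")
    post <- vapply(block, `[[`, TRUE, "post_sig")
    if (all(pre)) "early_component_in_all_datasets"
    else if (all(post)) "late_component_only"
    else "mixed_time_course"
  }
  dec$H2 <- tree_h2(s$rd)

  if (is.null(s$auc)) {
    dec$H3 <- dec$H4 <- "not_run_no_traces"
  } else {
    dec$H3 <- if (all(vapply(s$auc, `[[`, TRUE, "acc_sig")))
      "reduced_overall_force_inferred" else "not_supported"
    dec$H4 <- tree_h2(s$auc)
  }

  dec$H5 <- if (!isTRUE(s$h5$ran)) "not_tested_gate_failed"
  else if (s$h5$main_sig && !s$h5$int_sig) "attenuation_in_all_windows"
  else if (s$h5$int_sig) "attenuation_in_significant_windows"
  else "not_supported"

  dec$H6 <- if (is.null(s$h6)) "not_run_no_traces"
  else if (s$h6$sig) "covert_abortion_link_supported"
  else "not_significant_bayes_factor_reported"

  dec$H7 <- if (s$h7$sig) "errors_initiated_faster" else "not_supported"
  dec$H8 <- if (s$h8$sig) "errors_enacted_weaker" else "not_supported"

  tibble::tibble(hypothesis = names(dec),
                 decision = unlist(dec, use.names = FALSE))
}

#' @export
print.kf_report <- function(x, ...) {
  cat("<kf_report> registered analysis chain\n")
  cat(sprintf("  datasets: %s\n", paste(names(x$datasets), collapse = ", ")))
  print(x$decisions, n = Inf)
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Machine-readable report: configuration echo, selection log and
#' gates, matching/equivalence summaries per iteration, every test
#' statistic, and the decision labels.
#'
#' @param report A `kf_report`.
#' @param path Optional file path; when supplied the JSON is written
#'   there (invisibly returning the path), otherwise the JSON string is
#'   returned.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    config = unclass(report$config),
    selection = list(log = report$selection$log, gates = report$selection$gates),
    matching = lapply(report$matching, function(l) list(
      variable = l$variable, bound = l$bound, iterations = l$iterations,
      converged = l$converged, log = l$log, flagged = l$flagged)),
    tests = tidy.kf_report(report),
    decisions = report$decisions,
    notes = report$notes)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
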