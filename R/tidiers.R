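#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a paired t-test
#'
#' @param x A `kf_ttest`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `estimate`
#'   (mean difference), `dz`, `conf.low`, `conf.high`, `tail`.
#' @export
tidy.kf_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p,
                 estimate = x$mean_diff, dz = x$dz,
                 conf.low = x$ci[1], conf.high = x$ci[2], tail = x$tail)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x A `kf_anova`.
#' @param ... Unused.
#' @return Tibble with one row per effect (term, df, statistic, p.value,
#'   pes, gg_epsilon, p_gg, mauchly_p).
#' @export
tidy.kf_anova <- function(x, ...) {
  dplyr::rename(x$table, term = "effect", p.value = "p")
}

#' @rdname tidy.kf_anova
#' @export
glance.kf_anova <- function(x, ...) {
  tibble::tibble(n = x$n, dv = x$dv,
                 design = paste(x$within, collapse = " x "))
}

#' Tidy a correlation test
#'
#' @param x A `kf_cortest`.
#' @param ... Unused.
#' @export
tidy.kf_cortest <- function(x, ...) {
  tibble::tibble(estimate = x$r, statistic = x$statistic, df = x$df,
                 p.value = x$p, n = x$n, tail = x$tail)
}

#' Tidy a Bayes-factor result
#'
#' @param x A `kf_bayes`.
#' @param ... Unused.
#' @export
tidy.kf_bayes <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, bf01 = x$bf01,
                 prior = x$prior$family, prior_scale = x$prior[[2]],
                 tail = x$tail)
}

#' Tidy an equivalence (TOST) result
#'
#' @param x A `kf_equivalence`.
#' @param ... Unused.
#' @export
tidy.kf_equivalence <- function(x, ...) {
  tibble::tibble(bound = x$bound, df = x$df,
                 t_lower = x$t_lower, p_lower = x$p_lower,
                 t_upper = x$t_upper, p_upper = x$p_upper,
                 t_reported = x$t_reported, p_reported = x$p_reported,
                 pass = x$pass, n_offenders = length(x$offenders))
}

#' Collect every test in a pipeline report into one tibble
#'
#' @param x A `kf_report`.
#' @param ... Unused.
#' @return Tibble with columns `analysis`, `dataset`, `term`,
#'   `statistic`, `df1`, `df2`, `p.value`, `estimate`, `dz`, `pes`,
#'   `bf10`.
#' @export
tidy.kf_report <- function(x, ...) {
  rows <- list()
  add <- function(analysis, dataset, term, statistic = NA_real_,
                  df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                  estimate = NA_real_, dz = NA_real_, pes = NA_real_,
                  bf10 = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analysis = analysis, dataset = dataset, term = term,
      statistic = statistic, df1 = df1, df2 = df2, p.value = p,
      estimate = estimate, dz = dz, pes = pes, bf10 = bf10)
  }
  block <- function(analysis, lst) {
    for (ds in names(lst)) {
      a <- lst[[ds]]
      if (is.null(a)) next
      tab <- a$anova$table
      for (i in seq_len(nrow(tab))) {
        add(analysis, ds, tab$effect[i], tab$statistic[i], tab$df1[i],
            tab$df2[i], tab$p[i], pes = tab$pes[i])
      }
      for (w in names(a$followups)) {
        t <- a$followups[[w]]
        add(paste0(analysis, "_followup"), ds, w, t$statistic, t$df,
            p = t$p, estimate = t$mean_diff, dz = t$dz)
      }
    }
  }
  block("rd", x$rd)
  if (!is.null(x$auc)) block("auc", x$auc)
  if (!is.null(x$h1_bayes)) {
    for (ds in names(x$h1_bayes)) {
      add("rd_bayes_fallback", ds, "accuracy",
          bf10 = x$h1_bayes[[ds]]$bf$bf10)
    }
  }
  for (v in names(x$matching)) {
    eq <- x$matching[[v]]$equivalence
    add("equivalence", paste0(v, "_matched"), eq$reported, eq$t_reported,
        eq$df, p = eq$p_reported)
  }
  if (isTRUE(x$h5$ran)) {
    tab <- x$h5$anova$table
    for (i in seq_len(nrow(tab))) {
      add("windowed_force", "rt_matched", tab$effect[i], tab$statistic[i],
          tab$df1[i], tab$df2[i], tab$p[i], pes = tab$pes[i])
    }
  }
  if (!is.null(x$h6)) {
    add("delta_auc_correlation", "unmatched", "pearson",
        x$h6$test$statistic, x$h6$test$df, p = x$h6$test$p,
        estimate = x$h6$test$r,
        bf10 = if (!is.null(x$h6$bayes)) x$h6$bayes$bf10 else NA_real_)
  }
  add("rt", "unmatched", "correct_minus_error", x$h7$statistic, x$h7$df,
      p = x$h7$p, estimate = x$h7$mean_diff, dz = x$h7$dz)
  add("pf", "unmatched", "correct_minus_error", x$h8$statistic, x$h8$df,
      p = x$h8$p, estimate = x$h8$mean_diff, dz = x$h8$dz)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.kf_report
#' @export
glance.kf_report <- function(x, ...) {
  tibble::tibble(
    n_participants = length(unique(x$datasets$unmatched$participant_id)),
    n_trials_unmatched = nrow(x$datasets$unmatched),
    rt_match_converged = x$matching$rt$converged,
    pf_match_converged = x$matching$pf$converged,
    h1 = x$decisions$decision[x$decisions$hypothesis == "H1"])
}

#' Plot aggregated force profiles
#'
#' Grand-mean force profiles by accuracy (means of participant means),
#' peak-locked or target-locked depending on the time axis present.
#'
#' @param profiles Output of [cell_profiles()] or
#'   [aggregate_profiles()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  axis <- intersect(c("lag_ms", "time_ms"), names(profiles))[1]
  grand <- profiles |>
    dplyr::group_by(.data$outcome, .data[[axis]]) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(grand, ggplot2::aes(.data[[axis]], .data$value,
                                      colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (axis == "lag_ms") "time from force peak (ms)"
          else "time from target onset (ms)",
      y = "force", colour = "accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kf_match <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = sprintf("matched difference (correct - error) in %s",
                              toupper(attr(object, "variable"))),
                  y = "pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kf_report <- function(object, ...) {
  cells <- dplyr::bind_rows(lapply(names(object$rd), function(ds) {
    dplyr::mutate(object$rd[[ds]]$cells, dataset = ds)
  }))
  summ <- cells |>
    dplyr::group_by(.data$dataset, .data$outcome, .data$window) |>
    dplyr::summarise(rd = mean(.data$rd), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$window, .data$rd,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(x = "time window", y = "response duration (ms)",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}
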