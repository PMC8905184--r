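#' Interpolate a force trace onto a 1-ms grid
#'
#' Linear interpolation between adjacent samples; values requested
#' outside the recorded span are zero-filled and flagged as unobserved.
#' Interpolation at original sample times reproduces the original values
#' exactly, and a trace that is already on a 1-ms grid passes through
#' unchanged.
#'
#' @param times Sample times in ms, strictly increasing.
#' @param values Forces (a.u.), same length as `times`.
#' @param window Length-2 numeric, the requested time window in ms;
#'   defaults to the recorded span.
#' @return Tibble with `time_ms` (integer grid), `value`, `observed`.
#' @export
interpolate_1ms <- function(times, values, window = range(times)) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (window[2] < window[1]) rlang::abort("empty interpolation window.")
  grid <- seq(ceiling(window[1]), floor(window[2]), by = 1)
  if (!length(grid)) rlang::abort("empty interpolation window.")
  inside <- grid >= times[1] & grid <= times[length(times)]
  val <- numeric(length(grid))
  if (any(inside)) {
    val[inside] <- stats::approx(times, values, xout = grid[inside])$y
  }
  tibble::tibble(time_ms = grid, value = val, observed = inside)
}

#' Re-reference a 1-ms profile to the force peak
#'
#' Shifts the time axis of a target-locked profile so that lag 0 is the
#' first occurrence of the peak force, and windows it to
#' `window` (default -300..+300 ms). Lags outside the recorded span are
#' zero-filled and flagged.
#'
#' @param profile Tibble with `time_ms` and `value` (1-ms grid), as
#'   returned by [interpolate_1ms()].
#' @param time_to_peak Time (ms, same axis as `time_ms`) of the first
#'   peak-force occurrence.
#' @param window Length-2 lag window in ms.
#' @return Tibble with `lag_ms`, `value`, `observed`.
#' @export
peak_lock <- function(profile, time_to_peak, window = c(-300, 300)) {
  stopifnot(is.finite(time_to_peak))
  lags <- seq(window[1], window[2], by = 1)
  want <- time_to_peak + lags
  lo <- min(profile$time_ms); hi <- max(profile$time_ms)
  inside <- want >= lo & want <= hi
  val <- numeric(length(lags))
  if (any(inside)) {
    val[inside] <- stats::approx(profile$time_ms, profile$value,
                                 xout = want[inside])$y
  }
  tibble::tibble(lag_ms = lags, value = val, observed = inside)
}

#' Rescale a profile to fractions of its peak force
#'
#' @param profile Tibble with a `value` column.
#' @param pf Peak force (a.u.), must be positive.
#' @return `profile` with `value` divided by `pf`.
#' @export
relativize <- function(profile, pf) {
  if (!is.finite(pf) || pf <= 0) rlang::abort("`pf` must be positive.")
  profile$value <- profile$value / pf
  profile
}

#' Average profiles pointwise within cells
#'
#' Pointwise arithmetic mean of profile values across trials within the
#' grouping supplied in `...` (typically participant and accuracy); a
#' grand mean over participants is then the mean of participant means.
#'
#' @param profiles Long tibble of per-trial profiles containing a time
#'   axis column (`lag_ms` or `time_ms`) and `value`.
#' @param ... Grouping columns (tidy-select style), e.g.
#'   `participant_id, outcome`.
#' @return Tibble with the grouping columns, the time axis and mean
#'   `value`; cells are simply absent when no trial contributes.
#' @export
aggregate_profiles <- function(profiles, ...) {
  axis <- intersect(c("lag_ms", "time_ms"), names(profiles))[1]
  if (is.na(axis)) rlang::abort("`profiles` needs a `lag_ms` or `time_ms` column.")
  profiles |>
    dplyr::group_by(..., .data[[axis]]) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

# trapezoid on an equally spaced or arbitrary grid
.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Pre-/post-peak areas under a peak-locked profile
#'
#' Trapezoidal integrals of a peak-locked (usually relative) profile
#' over the pre-peak (`lag <= 0`) and post-peak (`lag >= 0`) halves of
#' the window. With relative profiles the units are fraction x ms.
#'
#' @param profile Tibble with `lag_ms` and `value` on a 1-ms grid.
#' @return One-row tibble: `auc_pre`, `auc_post`, `auc_total`
#'   (`auc_total = auc_pre + auc_post`).
#' @export
profile_auc <- function(profile) {
  profile <- dplyr::arrange(profile, .data$lag_ms)
  pre <- profile$lag_ms <= 0
  post <- profile$lag_ms >= 0
  a_pre <- .trapz(profile$lag_ms[pre], profile$value[pre])
  a_post <- .trapz(profile$lag_ms[post], profile$value[post])
  tibble::tibble(auc_pre = a_pre, auc_post = a_post,
                 auc_total = a_pre + a_post)
}

#' Mean forces in 20-ms windows counting back from the mean matched RT
#'
#' For the windowed follow-up analysis on RT-matched data: mean absolute
#' force in five consecutive 20-ms windows ending at the mean matched
#' response time ("99 to 80", "79 to 60", "59 to 40", "39 to 20" and
#' "19 to 0" ms before it).
#'
#' @param profile Target-locked tibble with `time_ms` and `value`
#'   (absolute force, 1-ms grid).
#' @param mean_matched_rt Mean RT (ms) of the RT-matched dataset.
#' @return Tibble with `window` (ordered factor, e.g. `"99-80"`) and
#'   `mean_force`.
#' @export
windowed_mean_forces <- function(profile, mean_matched_rt) {
  labels <- c("99-80", "79-60", "59-40", "39-20", "19-0")
  start_back <- c(99, 79, 59, 39, 19)
  end_back <- c(80, 60, 40, 20, 0)
  out <- lapply(seq_along(labels), function(k) {
    hi <- mean_matched_rt - end_back[k]
    lo <- mean_matched_rt - start_back[k]
    if (lo < min(profile$time_ms)) {
      rlang::abort("windowed analysis reaches before the recorded profile start.")
    }
    sel <- profile$time_ms >= lo & profile$time_ms <= hi
    tibble::tibble(window = labels[k], mean_force = mean(profile$value[sel]))
  })
  out <- dplyr::bind_rows(out)
  out$window <- factor(out$window, levels = labels)
  out
}

#' Aggregated 1-ms profiles per participant and outcome
#'
#' Efficient matrix-based computation of cell-mean profiles for a set of
#' classified trials: per-trial baseline-corrected traces of the
#' responding channel are interpolated to 1 ms, optionally peak-locked
#' and rescaled to fractions of the trial's peak force, then averaged
#' pointwise within participant x outcome cells.
#'
#' @param forces Long force-sample tibble.
#' @param features Classified feature rows (must contain `outcome`; only
#'   these trials enter).
#' @param lock `"peak"` (lag -300..300 ms around the first peak) or
#'   `"target"` (target onset..end of recording).
#' @param relative Divide each trial's profile by its peak force before
#'   averaging? Defaults to `TRUE` for peak-locked profiles.
#' @param n_baseline Post-target samples averaged as baseline.
#' @return Tibble: `participant_id`, `outcome`, `lag_ms`/`time_ms`,
#'   `value`.
#' @export
cell_profiles <- function(forces, features, lock = c("peak", "target"),
                          relative = (lock == "peak"), n_baseline = 10) {
  lock <- match.arg(lock)
  relative <- isTRUE(relative[1])
  keep <- features[!is.na(features$pf), ]
  parts <- split(keep, keep$participant_id)
  res <- lapply(parts, function(fe) {
    d <- forces[forces$participant_id == fe$participant_id[1] &
                  forces$trial_global %in% fe$trial_global, ]
    .cell_profiles_one(d, fe, lock, relative, n_baseline)
  })
  dplyr::bind_rows(res)
}

.cell_profiles_one <- function(d, fe, lock, relative, n_baseline) {
  pp <- .participant_profiles(d, fe, n_baseline)
  oc_by_col <- as.character(fe$outcome[pp$order])
  if (lock == "peak") {
    V <- .peak_lock_matrix(pp, relative)
    axis <- -300:300; axis_name <- "lag_ms"
  } else {
    V <- .target_lock_matrix(pp, relative)
    axis <- pp$grid[pp$grid >= 0]; axis_name <- "time_ms"
  }
  cells <- lapply(split(seq_len(ncol(V)), oc_by_col), function(cols) {
    rowMeans(V[, cols, drop = FALSE])
  })
  out <- dplyr::bind_rows(lapply(names(cells), function(oc) {
    tibble::tibble(participant_id = fe$participant_id[1], outcome = oc,
                   axis = axis, value = cells[[oc]])
  }))
  names(out)[names(out) == "axis"] <- axis_name
  out
}

# per-participant trace pass: baseline-corrected responding-channel
# traces interpolated to the 1-ms grid, plus per-trial peak metadata
.participant_profiles <- function(d, fe, n_baseline) {
  tm <- .trace_matrices(d)
  times <- tm$times
  ord <- match(tm$ids$trial_global, fe$trial_global)
  fe <- fe[ord, ]
  L <- .baseline_mat(tm$left, times, n_baseline)
  R <- .baseline_mat(tm$right, times, n_baseline)
  M <- L
  use_r <- fe$response_key == "right" & !is.na(fe$response_key)
  M[, use_r] <- R[, use_r]
  grid <- seq(min(times), max(times), by = 1)
  list(grid = grid, P = .interp_matrix(times, M, grid),
       pf = fe$pf, ttp = fe$time_to_peak,
       trial_global = fe$trial_global, order = ord)
}

.peak_lock_matrix <- function(pp, relative) {
  lags <- -300:300
  n_tr <- ncol(pp$P)
  rows <- outer(lags, pp$ttp - pp$grid[1] + 1, "+")
  ok <- rows >= 1 & rows <= length(pp$grid)
  rows[!ok] <- 1L
  V <- matrix(pp$P[as.vector(rows) +
                     rep((seq_len(n_tr) - 1L) * length(pp$grid),
                         each = length(lags))], nrow = length(lags))
  V[!ok] <- 0
  if (relative) V <- sweep(V, 2, pp$pf, "/")
  V
}

.target_lock_matrix <- function(pp, relative) {
  V <- pp$P[pp$grid >= 0, , drop = FALSE]
  if (relative) V <- sweep(V, 2, pp$pf, "/")
  V
}

# single pass over the traces for all datasets of a pipeline run:
# peak-locked relative cell means everywhere, target-locked absolute
# cell means for the RT-matched dataset (windowed follow-up analysis)
.analysis_profiles <- function(forces, datasets, n_baseline = 10) {
  union_fe <- dplyr::distinct(
    dplyr::bind_rows(datasets)[, c("participant_id", "trial_global",
                                   "response_key", "pf", "time_to_peak")])
  keys <- split(forces, forces$participant_id)
  peak <- list(); target <- list()
  for (pid_chr in names(keys)) {
    fe_p <- union_fe[union_fe$participant_id == unique(keys[[pid_chr]]$participant_id), ]
    if (!nrow(fe_p)) next
    d <- keys[[pid_chr]]
    d <- d[d$trial_global %in% fe_p$trial_global, ]
    pp <- .participant_profiles(d, fe_p, n_baseline)
    PL <- .peak_lock_matrix(pp, relative = TRUE)
    TL <- .target_lock_matrix(pp, relative = FALSE)
    tgrid <- pp$grid[pp$grid >= 0]
    for (ds in names(datasets)) {
      dfe <- datasets[[ds]]
      dfe <- dfe[dfe$participant_id == fe_p$participant_id[1], ]
      for (oc in unique(as.character(dfe$outcome))) {
        cols <- match(dfe$trial_global[dfe$outcome == oc], pp$trial_global)
        cols <- cols[!is.na(cols)]
        if (!length(cols)) next
        peak[[length(peak) + 1]] <- tibble::tibble(
          dataset = ds, participant_id = fe_p$participant_id[1],
          outcome = oc, lag_ms = -300:300,
          value = rowMeans(PL[, cols, drop = FALSE]))
        if (ds == "rt_matched") {
          target[[length(target) + 1]] <- tibble::tibble(
            dataset = ds, participant_id = fe_p$participant_id[1],
            outcome = oc, time_ms = tgrid,
            value = rowMeans(TL[, cols, drop = FALSE]))
        }
      }
    }
  }
  list(peak = dplyr::bind_rows(peak), target = dplyr::bind_rows(target))
}

# linear interpolation of every column of `mat` (sampled at `times`,
# equally spaced) onto `grid`; exact at the original sample times
.interp_matrix <- function(times, mat, grid) {
  dt <- times[2] - times[1]
  idx <- (grid - times[1]) / dt
  i <- pmin(floor(idx), length(times) - 2)
  w <- idx - i
  mat[i + 1, , drop = FALSE] * (1 - w) + mat[i + 2, , drop = FALSE] * w
}
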