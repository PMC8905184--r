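#' Baseline-correct force traces
#'
#' Subtracts, separately for every trial and channel, the mean of the
#' first 10 samples recorded at or after target onset, then clamps
#' negative values to zero (negative true forces cannot occur by design;
#' they only arise through the correction).
#'
#' @param forces Long tibble of force samples with columns
#'   `participant_id`, `trial_global`, `channel`, `time_ms_from_target`,
#'   `force_au` (the schema written by [simulate_cohort()]).
#' @param n_baseline Number of post-target samples averaged (default 10).
#' @return `forces` with `force_au` baseline-corrected.
#' @export
baseline_correct <- function(forces, n_baseline = 10) {
  forces |>
    dplyr::group_by(.data$participant_id, .data$trial_global, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      post <- which(d$time_ms_from_target >= 0)
      if (length(post) < n_baseline) {
        rlang::abort(sprintf(
          "trial %s/%s: fewer than %d samples after target onset; trial unusable.",
          key$participant_id, key$trial_global, n_baseline))
      }
      b <- mean(d$force_au[post[seq_len(n_baseline)]])
      d$force_au <- pmax(d$force_au - b, 0)
      d
    }) |>
    dplyr::ungroup()
}

#' Detect threshold onset and offset of a corrected force channel
#'
#' Onset is the first millisecond at which the linearly interpolated
#' force reaches `threshold`; offset is the last such millisecond in the
#' trial (so a dip below threshold between two supra-threshold lobes is
#' spanned). Times follow the input time axis (ms relative to target
#' onset).
#'
#' @param times Sample times in ms, strictly increasing, equally spaced.
#' @param values Baseline-corrected forces (a.u.), same length.
#' @param threshold Response threshold in a.u. (default 0.25).
#' @return A one-row tibble with `onset_time` and `offset_time` (`NA` if
#'   the threshold is never reached).
#' @export
detect_onset_offset <- function(times, values, threshold = 0.25) {
  tibble::tibble(
    onset_time = .first_crossing(times, values, threshold),
    offset_time = .last_crossing(times, values, threshold)
  )
}

# first integer ms at which the 1-ms linear interpolation >= thr
.first_crossing <- function(times, values, thr) {
  i <- which(values >= thr)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  if (i == 1) return(times[1])
  x <- times[i - 1] +
    (thr - values[i - 1]) / (values[i] - values[i - 1]) *
    (times[i] - times[i - 1])
  ceiling(x)
}

# last integer ms at which the 1-ms linear interpolation >= thr
.last_crossing <- function(times, values, thr) {
  i <- which(values >= thr)
  if (!length(i)) return(NA_real_)
  i <- i[length(i)]
  if (i == length(values)) return(times[i])
  x <- times[i] +
    (values[i] - thr) / (values[i] - values[i + 1]) *
    (times[i + 1] - times[i])
  floor(x)
}

# vectorised versions over the columns of a samples x trials matrix
.first_crossing_mat <- function(times, mat, thr) {
  n_s <- nrow(mat)
  hit <- mat >= thr
  any_hit <- colSums(hit) > 0
  out <- rep(NA_real_, ncol(mat))
  if (!any(any_hit)) return(out)
  fi <- apply(hit[, any_hit, drop = FALSE], 2, which.max)
  j <- which(any_hit)
  at_start <- fi == 1
  out[j[at_start]] <- times[1]
  k <- j[!at_start]; i <- fi[!at_start]
  if (length(k)) {
    v1 <- mat[cbind(i - 1, k)]; v2 <- mat[cbind(i, k)]
    x <- times[i - 1] + (thr - v1) / (v2 - v1) * (times[i] - times[i - 1])
    out[k] <- ceiling(x)
  }
  out
}

.last_crossing_mat <- function(times, mat, thr) {
  n_s <- nrow(mat)
  hit <- mat >= thr
  any_hit <- colSums(hit) > 0
  out <- rep(NA_real_, ncol(mat))
  if (!any(any_hit)) return(out)
  li <- n_s + 1 - apply(hit[n_s:1, any_hit, drop = FALSE], 2, which.max)
  j <- which(any_hit)
  at_end <- li == n_s
  out[j[at_end]] <- times[n_s]
  k <- j[!at_end]; i <- li[!at_end]
  if (length(k)) {
    v1 <- mat[cbind(i, k)]; v2 <- mat[cbind(i + 1, k)]
    x <- times[i] + (v1 - thr) / (v1 - v2) * (times[i + 1] - times[i])
    out[k] <- floor(x)
  }
  out
}

#' Extract per-trial response features from force recordings
#'
#' Runs the offline feature chain on every trial: baseline correction
#' against the first 10 post-target samples of each channel (clamped at
#' zero), identification of the responding channel (the first channel
#' whose corrected force reaches the response threshold), onset/offset
#' detection at 1-ms resolution, peak force and time to the first peak,
#' the pre-/post-peak split of the response duration, and the covert
#' flag for low-threshold activity on the unpressed key.
#'
#' @param forces Long tibble of force samples (see [simulate_cohort()]).
#' @param response_threshold Registration threshold in a.u. (default 0.25).
#' @param covert_threshold Low threshold in a.u. marking covert activity
#'   on the other key (default 0.1).
#' @param n_baseline Number of post-target samples averaged as baseline.
#' @return One row per trial: identifiers, `response_key`, `onset_time`,
#'   `offset_time`, `rt`, `rd`, `rd_pre_peak`, `rd_post_peak`, `pf`,
#'   `time_to_peak`, `covert_other_key`, `supra_threshold`. Trials
#'   without a supra-threshold response have `NA` features. Durations
#'   satisfy `rd == rd_pre_peak + rd_post_peak` exactly.
#' @export
extract_features <- function(forces, response_threshold = 0.25,
                             covert_threshold = 0.1, n_baseline = 10) {
  parts <- split(forces, forces$participant_id)
  dplyr::bind_rows(lapply(parts, .extract_features_one,
                          thr = response_threshold,
                          low = covert_threshold,
                          n_baseline = n_baseline))
}

.trace_matrices <- function(d) {
  d <- dplyr::arrange(d, .data$trial_global, .data$channel, .data$sample_idx)
  times <- sort(unique(d$time_ms_from_target))
  n_s <- length(times)
  first <- d$sample_idx == d$sample_idx[1] & d$channel == d$channel[1]
  ids <- d[first, c("participant_id", "block", "trial_in_block",
                    "trial_global")]
  n_tr <- nrow(ids)
  if (nrow(d) != n_s * 2L * n_tr) {
    rlang::abort("irregular force table: every trial needs both channels on a common sample grid.")
  }
  f <- matrix(d$force_au, nrow = n_s)  # cols: (trial1 L, trial1 R, trial2 L, ...)
  list(times = times,
       left = f[, seq(1, 2 * n_tr, by = 2), drop = FALSE],
       right = f[, seq(2, 2 * n_tr, by = 2), drop = FALSE],
       ids = ids)
}

.baseline_mat <- function(mat, times, n_baseline) {
  post <- which(times >= 0)
  if (length(post) < n_baseline) {
    rlang::abort("fewer post-target samples than the baseline window; trials unusable.")
  }
  b <- colMeans(mat[post[seq_len(n_baseline)], , drop = FALSE])
  pmax(sweep(mat, 2, b), 0)
}

.extract_features_one <- function(d, thr, low, n_baseline) {
  tm <- .trace_matrices(d)
  times <- tm$times
  L <- .baseline_mat(tm$left, times, n_baseline)
  R <- .baseline_mat(tm$right, times, n_baseline)

  on_l <- .first_crossing_mat(times, L, thr)
  on_r <- .first_crossing_mat(times, R, thr)
  # responding channel: the first to cross; ties resolved to the left key
  resp_left <- !is.na(on_l) & (is.na(on_r) | on_l <= on_r)
  resp_right <- !is.na(on_r) & !resp_left
  n_tr <- ncol(L)
  response_key <- rep(NA_character_, n_tr)
  response_key[resp_left] <- "left"
  response_key[resp_right] <- "right"
  supra <- !is.na(response_key)

  onset <- ifelse(resp_left, on_l, ifelse(resp_right, on_r, NA_real_))
  off_l <- .last_crossing_mat(times, L, thr)
  off_r <- .last_crossing_mat(times, R, thr)
  offset <- ifelse(resp_left, off_l, ifelse(resp_right, off_r, NA_real_))

  pick <- function(ml, mr) {
    out <- matrix(NA_real_, nrow(ml), n_tr)
    out[, resp_left] <- ml[, resp_left]
    out[, resp_right] <- mr[, resp_right]
    out
  }
  M <- pick(L, R)
  pf <- rep(NA_real_, n_tr)
  ttp <- rep(NA_real_, n_tr)
  if (any(supra)) {
    sub <- M[, supra, drop = FALSE]
    pf[supra] <- apply(sub, 2, max)
    # first occurrence of the maximum defines the time to peak
    ttp[supra] <- times[apply(sub, 2, which.max)]
  }

  other_max_l <- apply(L, 2, max)
  other_max_r <- apply(R, 2, max)
  other_max <- ifelse(resp_left, other_max_r,
                      ifelse(resp_right, other_max_l, NA_real_))

  dplyr::bind_cols(
    tm$ids,
    tibble::tibble(
      response_key = response_key,
      onset_time = onset, offset_time = offset,
      rt = onset, rd = offset - onset,
      rd_pre_peak = ttp - onset, rd_post_peak = offset - ttp,
      pf = pf, time_to_peak = ttp,
      covert_other_key = !is.na(other_max) & other_max >= low,
      supra_threshold = supra
    )
  )
}
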