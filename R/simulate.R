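#' Simulate a cohort of two-channel force recordings
#'
#' Generates a synthetic cohort with the structure the analysis chain
#' assumes: participants work through one practice block and a series of
#' experimental blocks of speeded letter-classification trials, pressing
#' one of two isometric force keys. Each registered response is a
#' raised-cosine force pulse whose threshold-crossing times and maximum
#' reproduce the trial's latent response time, response duration and peak
#' force (see [pulse_shape()]); commission errors, omissions,
#' anticipations and covert sub-threshold activity on the unpressed key
#' occur at configurable rates. Ground truth for every latent quantity is
#' returned alongside the data.
#'
#' @param config A [cohort_config()].
#' @param effects An [effect_config()].
#' @param seed Integer seed; fixing it makes the output reproducible.
#' @param emit `"traces"` returns the sampled force series plus trial
#'   metadata and ground truth; `"features"` skips trace rendering and
#'   returns idealised per-trial features in the schema of
#'   [extract_features()], which is convenient for large simulation
#'   studies of the selection, matching and inference stages.
#' @return A list of class `kf_cohort` with elements `trials` (metadata),
#'   `truth` (per-trial latents), `truth_participants` (latent means),
#'   `config`, `effects`, and -- depending on `emit` -- `forces` (long
#'   tibble of force samples) or `features`.
#' @examples
#' co <- simulate_cohort(cohort_config(n_participants = 2, n_blocks = 1),
#'                       seed = 1)
#' dplyr::count(co$trials, online_outcome)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            effects = effect_config(),
                            seed = NULL,
                            emit = c("traces", "features")) {
  stopifnot(inherits(config, "kf_cohort_config"),
            inherits(effects, "kf_effect_config"))
  emit <- match.arg(emit)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pp <- .draw_participants(config, effects)
  tr <- .draw_trials(config, effects, pp)

  truth <- dplyr::select(
    tr, "participant_id", "block", "trial_global", "outcome_latent",
    rt_latent = "rt", rd_latent = "rd", pf_latent = "pf",
    covert = "covert", covert_amp = "covert_amp"
  )

  trials <- dplyr::transmute(
    tr,
    participant_id = .data$participant_id, block = .data$block,
    trial_in_block = .data$trial_in_block,
    trial_global = .data$trial_global,
    is_practice = .data$block == 0L,
    target_letter = .data$target_letter,
    distractor_letter = .data$distractor_letter,
    correct_key = .data$correct_key,
    response_key_online = .data$response_key_online,
    online_outcome = .data$online_outcome
  )

  out <- list(trials = trials, truth = truth, truth_participants = pp,
              config = config, effects = effects, seed = seed)
  if (emit == "traces") {
    out$forces <- .render_forces(config, effects, tr)
  } else {
    out$features <- .latent_features(config, effects, tr)
  }
  structure(out, class = "kf_cohort")
}

#' @export
print.kf_cohort <- function(x, ...) {
  cat(sprintf("<kf_cohort> %d participants, %d experimental blocks x %d trials (+%d practice)\n",
              x$config$n_participants, x$config$n_blocks,
              x$config$trials_per_block, x$config$practice_trials))
  cat(sprintf("  contains: %s\n",
              paste(intersect(c("forces", "features"), names(x)), collapse = ", ")))
  invisible(x)
}

# lognormal draw parameterised by its mean and sd: strictly positive and
# right-skewed, as empirical duration distributions are, with the latent
# participant mean reproduced exactly (no truncation distortion)
.rlnorm_ms <- function(n, mean, sd) {
  if (length(mean) == 1) mean <- rep(mean, n)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# truncated-normal draw via inverse cdf (deterministic under set.seed)
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.target_letters <- c("T", "N", "V", "K")
.distractor_letters <- c("O", "W", "X", "U", "Z", "Y", "H", "A")

.draw_participants <- function(config, effects) {
  P <- config$n_participants
  e <- effects
  d_rt <- e$rt_mean_correct - e$rt_mean_error
  d_rd <- e$rd_mean_correct - e$rd_mean_error
  d_pf <- e$pf_mean_correct - e$pf_mean_error
  rt_c <- .rtnorm(P, e$rt_mean_correct, e$rt_sd_between, 250, 700)
  rd_c <- .rtnorm(P, e$rd_mean_correct, e$rd_sd_between, 60, 300)
  pf_c <- .rtnorm(P, e$pf_mean_correct, e$pf_sd_between, 0.30, 1.20)
  tibble::tibble(
    participant_id = seq_len(P),
    # letter-to-key mapping alternates across recruitment
    mapping = rep_len(c("TN_left", "TN_right"), P),
    rt_mean_correct = rt_c,
    rt_mean_error = pmax(150, rt_c - stats::rnorm(P, d_rt, e$rt_sd_effect)),
    rd_mean_correct = rd_c,
    rd_mean_error = pmax(24, rd_c - stats::rnorm(P, d_rd, e$rd_sd_effect)),
    pf_mean_correct = pf_c,
    pf_mean_error = pmax(0.28, pf_c - stats::rnorm(P, d_pf, e$pf_sd_effect)),
    p_commission = .rtnorm(P, e$p_commission, e$p_commission_sd, 0.005, 0.40),
    p_covert = .rtnorm(P, e$p_covert_correct, e$p_covert_sd, 0, 1)
  )
}

.draw_trials <- function(config, effects, pp) {
  e <- effects
  blocks <- c(0L, seq_len(config$n_blocks))
  n_per_block <- c(config$practice_trials,
                   rep(config$trials_per_block, config$n_blocks))
  per_part <- tibble::tibble(
    block = rep(blocks, n_per_block),
    trial_in_block = unlist(lapply(n_per_block, seq_len), use.names = FALSE)
  )
  n_t <- nrow(per_part)
  tr <- tidyr::crossing(participant_id = pp$participant_id, per_part) |>
    dplyr::arrange(.data$participant_id, .data$block, .data$trial_in_block) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(trial_global = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(pp, by = "participant_id")

  n <- nrow(tr)
  tr$target_letter <- sample(.target_letters, n, replace = TRUE)
  tr$distractor_letter <- sample(.distractor_letters, n, replace = TRUE)
  left_targets <- ifelse(tr$mapping == "TN_left",
                         tr$target_letter %in% c("T", "N"),
                         tr$target_letter %in% c("V", "K"))
  tr$correct_key <- ifelse(left_targets, "left", "right")

  u <- stats::runif(n)
  tr$outcome_latent <- dplyr::case_when(
    u < e$p_anticipate ~ "anticipatory",
    u < e$p_anticipate + e$p_omit ~ "omission",
    u < e$p_anticipate + e$p_omit + tr$p_commission ~ "commission",
    TRUE ~ "correct"
  )
  err <- tr$outcome_latent == "commission"
  responds <- tr$outcome_latent != "omission"

  tr$rt <- .rtnorm(n, ifelse(err, tr$rt_mean_error, tr$rt_mean_correct),
                   e$rt_sd_within, 150, 900)
  tr$rd <- .rlnorm_ms(n, ifelse(err, tr$rd_mean_error, tr$rd_mean_correct),
                      e$rd_sd_within)
  tr$pf <- .rtnorm(n, ifelse(err, tr$pf_mean_error, tr$pf_mean_correct),
                   e$pf_sd_within, 0.27, 1.50)
  ant <- tr$outcome_latent == "anticipatory"
  tr$rt[ant] <- stats::runif(sum(ant), -config$fixation + 150, -20)
  tr$rt[!responds] <- NA_real_
  tr$rd[!responds] <- NA_real_
  tr$pf[!responds] <- NA_real_

  if (e$rt_pre_error_speedup > 0) {
    nxt_err <- dplyr::lead(err, default = FALSE) &
      dplyr::lead(tr$participant_id, default = -1L) == tr$participant_id
    tr$rt[nxt_err & responds] <- tr$rt[nxt_err & responds] - e$rt_pre_error_speedup
  }

  tr$response_key <- dplyr::case_when(
    !responds ~ NA_character_,
    err ~ ifelse(tr$correct_key == "left", "right", "left"),
    TRUE ~ tr$correct_key
  )

  # covert sub-threshold activity on the unpressed key of correct trials
  cov <- tr$outcome_latent == "correct" & stats::runif(n) < tr$p_covert
  tr$covert <- cov
  tr$covert_amp <- ifelse(cov, stats::runif(n, e$covert_amp_range[1],
                                            e$covert_amp_range[2]), NA_real_)
  tr$covert_onset <- ifelse(cov, tr$rt + stats::rnorm(n, 0, 20), NA_real_)
  tr$covert_width <- ifelse(cov, pmax(20, 0.6 * tr$rd), NA_real_)

  # online registration outcome (response before the deadline)
  registered <- responds & tr$rt <= config$deadline
  tr$response_key_online <- ifelse(registered, tr$response_key, NA_character_)
  tr$online_outcome <- dplyr::case_when(
    ant ~ "anticipatory",
    !responds | tr$rt > config$deadline ~ "omission",
    err ~ "commission",
    TRUE ~ "correct"
  )
  tr
}

# sampled force series for one cohort, long format, chunked by participant
.render_forces <- function(config, effects, tr) {
  tt <- seq(-config$fixation, config$record_until, by = config$sampling_interval)
  chunks <- lapply(split(tr, tr$participant_id), function(d) {
    .render_participant(d, tt, effects)
  })
  dplyr::bind_rows(chunks)
}

.render_participant <- function(d, tt, effects) {
  n_s <- length(tt)
  n_tr <- nrow(d)
  mk <- function() matrix(0, nrow = n_s, ncol = n_tr)
  left <- mk(); right <- mk()

  resp <- which(!is.na(d$rt))
  for (side in c("left", "right")) {
    rows <- resp[d$response_key[resp] == side]
    if (length(rows)) {
      vals <- .pulse_matrix(tt, d$rt[rows], d$rd[rows], d$pf[rows],
                            effects$pre_peak_fraction, 0.25)
      if (side == "left") left[, rows] <- vals else right[, rows] <- vals
    }
    crows <- which(d$covert & d$response_key != side)
    if (length(crows)) {
      vals <- .pulse_matrix(tt, d$covert_onset[crows], d$covert_width[crows],
                            d$covert_amp[crows], effects$pre_peak_fraction, 0.05)
      if (side == "left") left[, crows] <- left[, crows] + vals
      else right[, crows] <- right[, crows] + vals
    }
  }

  noise <- function() {
    if (effects$baseline_noise_sd > 0)
      matrix(stats::rnorm(n_s * n_tr, 0, effects$baseline_noise_sd), n_s)
    else 0
  }
  left <- pmax(left + effects$baseline_level + noise(), 0)
  right <- pmax(right + effects$baseline_level + noise(), 0)

  tibble::tibble(
    participant_id = rep(d$participant_id, each = 2L * n_s),
    block = rep(d$block, each = 2L * n_s),
    trial_in_block = rep(d$trial_in_block, each = 2L * n_s),
    trial_global = rep(d$trial_global, each = 2L * n_s),
    channel = rep(rep(c("left", "right"), each = n_s), n_tr),
    sample_idx = rep.int(rep(seq_len(n_s) - 1L, 2L), n_tr),
    time_ms_from_target = rep.int(rep(tt, 2L), n_tr),
    force_au = as.vector(rbind(left, right))
  )
}

# raised-cosine pulses for many trials at once (samples x trials)
.pulse_matrix <- function(tt, onset, width, amp, pre, thr) {
  n_s <- length(tt); m <- length(onset)
  q <- acos(1 - 2 * thr / amp) / pi
  p <- acos(2 * thr / amp - 1) / pi
  peak <- onset + pre * width
  rise <- pre * width / (1 - q)
  fall <- (1 - pre) * width / p
  t0 <- peak - rise
  T_ <- matrix(tt, n_s, m)
  PK <- matrix(peak, n_s, m, byrow = TRUE)
  T0 <- matrix(t0, n_s, m, byrow = TRUE)
  RI <- matrix(rise, n_s, m, byrow = TRUE)
  FA <- matrix(fall, n_s, m, byrow = TRUE)
  A <- matrix(amp, n_s, m, byrow = TRUE)
  out <- matrix(0, n_s, m)
  up <- T_ >= T0 & T_ <= PK
  dn <- T_ > PK & T_ <= PK + FA
  out[up] <- (A[up] / 2) * (1 - cos(pi * (T_[up] - T0[up]) / RI[up]))
  out[dn] <- (A[dn] / 2) * (1 + cos(pi * (T_[dn] - PK[dn]) / FA[dn]))
  out
}

# idealised features straight from the latents (schema of extract_features)
.latent_features <- function(config, effects, tr) {
  pre <- effects$pre_peak_fraction
  tibble::tibble(
    participant_id = tr$participant_id, block = tr$block,
    trial_in_block = tr$trial_in_block, trial_global = tr$trial_global,
    response_key = tr$response_key,
    onset_time = tr$rt,
    offset_time = tr$rt + tr$rd,
    rt = tr$rt, rd = tr$rd,
    rd_pre_peak = pre * tr$rd,
    rd_post_peak = (1 - pre) * tr$rd,
    pf = tr$pf,
    time_to_peak = tr$rt + pre * tr$rd,
    covert_other_key = tr$covert & !is.na(tr$covert_amp) &
      tr$covert_amp >= 0.1,
    supra_threshold = !is.na(tr$rt)
  )
}
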