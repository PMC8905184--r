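#' Cohort design configuration
#'
#' Describes the timing and size of a simulated force-key experiment:
#' a practice block followed by experimental blocks of speeded
#' four-letter choice trials, with two isometric force keys sampled at
#' 250 Hz from fixation onset until well after the response deadline.
#'
#' @param n_participants Number of participants.
#' @param n_blocks Number of experimental blocks (default 17).
#' @param trials_per_block Trials per experimental block (default 64).
#' @param practice_trials Trials in the single practice block (default 32).
#' @param sampling_interval Force sampling interval in ms (default 4,
#'   i.e. 250 Hz).
#' @param fixation Fixation duration in ms (default 500).
#' @param deadline Response deadline in ms after target onset (default 600).
#' @param iti Inter-trial interval in ms during which force is still
#'   recorded (default 1000).
#' @param record_until End of the recorded, target-locked analysis window
#'   in ms after target onset (default 1600).
#' @return A list of class `kf_cohort_config`.
#' @export
cohort_config <- function(n_participants = 34, n_blocks = 17,
                          trials_per_block = 64, practice_trials = 32,
                          sampling_interval = 4, fixation = 500,
                          deadline = 600, iti = 1000, record_until = 1600) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    practice_trials = as.integer(practice_trials),
    sampling_interval = sampling_interval,
    fixation = fixation, deadline = deadline, iti = iti,
    record_until = record_until
  )
  stopifnot(cfg$n_participants >= 1, cfg$n_blocks >= 1,
            cfg$trials_per_block >= 1, cfg$practice_trials >= 0,
            sampling_interval > 0)
  for (d in c("fixation", "deadline", "iti", "record_until")) {
    if (cfg[[d]] <= 0 || cfg[[d]] %% sampling_interval != 0) {
      rlang::abort(sprintf(
        "`%s` must be a positive multiple of `sampling_interval` (%g ms).",
        d, sampling_interval))
    }
  }
  structure(cfg, class = "kf_cohort_config")
}

#' Effect-structure configuration for the cohort generator
#'
#' Latent behavioural structure injected into simulated cohorts. The
#' location defaults are the unmatched condition means of the study this
#' package's analysis chain targets: correct responses around 449 ms
#' response time, 0.54 a.u. peak force and 145 ms response duration;
#' commission errors around 436 ms, 0.43 a.u. and 115 ms. Accuracy
#' effects are injected at the latent level (per-trial onset, width and
#' amplitude of the force pulse), so parameter recovery is well defined.
#'
#' Between-subject variation draws participant means from truncated
#' normal distributions; `*_sd_effect` terms add participant-level
#' heterogeneity to the accuracy effects, which is what paired
#' standardized effect sizes are sensitive to. Defaults for the rate
#' parameters mirror the reported prevalences: 9.4% commission errors
#' (s.d. 5.6%), 9.8% omissions, under 0.1% anticipations, and a 3.11%
#' mean rate (s.d. 4.07%, truncated at zero) of covert sub-threshold
#' activity on the unpressed key in correct trials.
#'
#' @param rt_mean_correct,rt_mean_error Mean response time (ms).
#' @param pf_mean_correct,pf_mean_error Mean peak force (a.u.); must
#'   exceed the 0.25 a.u. response threshold.
#' @param rd_mean_correct,rd_mean_error Mean response duration (ms).
#' @param pre_peak_fraction Fraction of the response duration spent
#'   before the force peak (default 55/130, the ratio of the reported
#'   pre- and post-peak duration means).
#' @param rt_sd_within,rd_sd_within,pf_sd_within Trial-to-trial s.d.
#' @param rt_sd_between,rd_sd_between,pf_sd_between Between-participant
#'   s.d. of the condition means.
#' @param rt_sd_effect,rd_sd_effect,pf_sd_effect Between-participant s.d.
#'   of the accuracy effect.
#' @param p_commission,p_commission_sd Mean and between-participant s.d.
#'   of the commission-error probability.
#' @param p_omit Probability of an omission (no supra-threshold response).
#' @param p_anticipate Probability of a supra-threshold crossing during
#'   fixation.
#' @param p_covert_correct,p_covert_sd Mean and between-participant s.d.
#'   of the probability that a correct trial carries covert sub-threshold
#'   activity on the other key.
#' @param covert_amp_range Range (a.u.) of covert pulse amplitudes;
#'   must stay below the 0.25 a.u. response threshold.
#' @param baseline_level Resting force level (a.u.) on both keys.
#' @param baseline_noise_sd Gaussian sensor noise s.d. (a.u.).
#' @param rt_pre_error_speedup Optional pre-error speeding (ms subtracted
#'   from the response time of trials that immediately precede an
#'   error); default 0 (off).
#' @return A list of class `kf_effect_config`.
#' @export
effect_config <- function(rt_mean_correct = 449, rt_mean_error = 436,
                          pf_mean_correct = 0.54, pf_mean_error = 0.43,
                          rd_mean_correct = 145, rd_mean_error = 115,
                          pre_peak_fraction = 55 / 130,
                          rt_sd_within = 60, rt_sd_between = 40,
                          rt_sd_effect = 10,
                          rd_sd_within = 30, rd_sd_between = 25,
                          rd_sd_effect = 10,
                          pf_sd_within = 0.18, pf_sd_between = 0.08,
                          pf_sd_effect = 0.07,
                          p_commission = 0.094, p_commission_sd = 0.056,
                          p_omit = 0.098, p_anticipate = 0.001,
                          p_covert_correct = 0.0311, p_covert_sd = 0.0407,
                          covert_amp_range = c(0.1, 0.249),
                          baseline_level = 0.05, baseline_noise_sd = 0.01,
                          rt_pre_error_speedup = 0) {
  eff <- as.list(environment())
  probs <- c(p_commission, p_omit, p_anticipate, p_covert_correct)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_commission + p_omit + p_anticipate < 1,
            pre_peak_fraction > 0, pre_peak_fraction < 1,
            length(covert_amp_range) == 2,
            covert_amp_range[1] < covert_amp_range[2],
            baseline_noise_sd >= 0, baseline_level >= 0)
  if (pf_mean_correct <= 0.25 || pf_mean_error <= 0.25) {
    rlang::abort("Mean peak forces must exceed the 0.25 a.u. response threshold; sub-threshold amplitudes cannot register as responses.")
  }
  if (covert_amp_range[1] < 0.1 || covert_amp_range[2] >= 0.25) {
    rlang::abort("`covert_amp_range` must lie in [0.1, 0.25) a.u.")
  }
  structure(eff, class = "kf_effect_config")
}
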