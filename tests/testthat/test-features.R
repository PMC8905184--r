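times4 <- seq(-500, 1600, by = 4)

test_that("baseline correction subtracts the post-target window and clamps", {
  tt <- seq(-500, 100, by = 4)
  # constant trace at 0.30: baseline equals the signal, everything zero
  tr <- toy_trace(tt, rep(0.30, length(tt)), rep(0.30, length(tt)))
  out <- baseline_correct(tr)
  expect_true(all(out$force_au == 0))
  # first 10 post-target samples at 0.10, later plateau at 0.60
  left <- ifelse(tt >= 0 & tt < 40, 0.10, ifelse(tt >= 40, 0.60, 0.10))
  tr2 <- toy_trace(tt, left, rep(0, length(tt)))
  out2 <- baseline_correct(tr2)
  plateau <- out2$force_au[out2$channel == "left" &
                             out2$time_ms_from_target >= 40]
  expect_equal(unique(plateau), 0.50)
  # too few post-target samples is an error
  expect_error(baseline_correct(toy_trace(seq(-40, 20, 4), rep(0, 16),
                                          rep(0, 16))), "unusable")
})

test_that("clamped noise behaves like a half-normal", {
  set.seed(42)
  tt <- seq(-500, 1600, by = 4)
  n <- length(tt)
  tr <- toy_trace(tt, rnorm(n, 0, 0.05), rnorm(n, 0, 0.05))
  out <- baseline_correct(tr)
  expect_true(all(out$force_au >= 0))
  # mean of max(0, x) for a centred gaussian is sd/sqrt(2*pi); the
  # estimated baseline adds jitter of order sd/sqrt(10)
  expect_lt(abs(mean(out$force_au) - 0.05 / sqrt(2 * pi)), 0.01)
})

test_that("onset and offset follow first/last 1-ms crossings", {
  out <- detect_onset_offset(c(0, 4, 8, 12), c(0, 0.3, 0.3, 0))
  expect_equal(out$onset_time, 4)
  expect_equal(out$offset_time, 8)
  expect_true(is.na(detect_onset_offset(c(0, 4, 8), c(0.1, 0.2, 0.1))$onset_time))
  # two lobes separated by a sub-threshold dip: offset in the second lobe
  tt <- seq(0, 60, 4)
  v <- c(0, 0.3, 0.4, 0.3, 0.1, 0.1, 0.1, 0.3, 0.5, 0.3, 0, 0, 0, 0, 0, 0)
  out2 <- detect_onset_offset(tt, v)
  oracle <- oracle_crossings(tt, v, 0.25)
  expect_equal(out2$onset_time, oracle[1])
  expect_equal(out2$offset_time, oracle[2])
  expect_gt(out2$offset_time, 30)
})

test_that("closed-form crossings equal the interpolate-then-scan oracle", {
  set.seed(7)
  for (i in 1:60) {
    tt <- seq(0, 200, by = 4)
    v <- pmax(0, stats::filter(rnorm(length(tt), 0.18, 0.12), rep(1 / 3, 3),
                               sides = 2))
    v[is.na(v)] <- 0
    ours <- detect_onset_offset(tt, v)
    orc <- oracle_crossings(tt, v, 0.25)
    expect_equal(ours$onset_time, orc[1])
    expect_equal(ours$offset_time, orc[2])
  }
})

test_that("a symmetric triangle pulse yields the textbook features", {
  # linear rise over 140 ms to an apex on the sample grid, mirrored fall
  tt <- seq(-500, 1600, by = 4)
  apex <- 0.95
  ramp <- function(t) {
    ifelse(t >= 332 & t <= 472, (t - 332) / 140 * apex,
           ifelse(t > 472 & t <= 612, (612 - t) / 140 * apex, 0))
  }
  v <- ramp(tt)
  tr <- toy_trace(tt, v, rep(0, length(tt)))
  fe <- extract_features(tr)
  # threshold 0.25 crossed at 332 + 0.25/0.95*140 = 368.8 -> first ms 369
  expect_equal(fe$rt, 369)
  expect_equal(fe$offset_time, 575)
  expect_equal(fe$rd, fe$rd_pre_peak + fe$rd_post_peak)
  expect_equal(fe$time_to_peak, 472)
  expect_equal(fe$pf, apex)
  expect_equal(fe$rd_pre_peak, fe$rd_post_peak)  # symmetric pulse
  expect_equal(fe$response_key, "left")
  expect_false(fe$covert_other_key)
})

test_that("plateaus at peak force resolve to the first occurrence", {
  tt <- seq(-500, 1600, by = 4)
  v <- ifelse(tt >= 400 & tt <= 440, 0.6, 0)
  fe <- extract_features(toy_trace(tt, v, rep(0, length(tt))))
  expect_equal(fe$time_to_peak, 400)
  expect_equal(fe$pf, 0.6)
})

test_that("noise-free generator round trip recovers the latents", {
  eff <- effect_config(baseline_noise_sd = 0, baseline_level = 0)
  co <- simulate_cohort(cohort_config(n_participants = 2, n_blocks = 2),
                        eff, seed = 77)
  fe <- extract_features(co$forces)
  j <- dplyr::inner_join(fe, co$truth, by = c("participant_id", "trial_global"))
  j <- j[!is.na(j$rt_latent) & j$outcome_latent %in% c("correct", "commission"), ]
  expect_gt(nrow(j), 100)
  # 1-ms grid semantics quantize each crossing (plus a chord error well
  # below one interpolation step); the duration combines both ends
  expect_lte(max(abs(j$rt - j$rt_latent)), 1.01)
  expect_lte(max(abs(j$rd - j$rd_latent)), 2.02)
  typical <- j$rd_latent >= 100
  expect_lte(max(abs(j$pf - j$pf_latent)[typical]), 0.001)
  expect_lte(max(abs(j$pf - j$pf_latent)), 0.005)
  expect_true(all(j$rd == j$rd_pre_peak + j$rd_post_peak))
  expect_true(all(j$onset_time <= j$time_to_peak &
                    j$time_to_peak <= j$offset_time))
  om <- dplyr::inner_join(fe, co$truth[co$truth$outcome_latent == "omission", ],
                          by = c("participant_id", "trial_global"))
  expect_true(all(!om$supra_threshold))
})

test_that("interpolation is linear, exact at samples, and identity at 1 ms", {
  out <- interpolate_1ms(c(4, 8), c(0.2, 0.6))
  expect_equal(out$value[out$time_ms == 5], 0.3)
  expect_equal(out$value[out$time_ms == 4], 0.2)
  expect_equal(out$value[out$time_ms == 8], 0.6)
  # flat segment stays flat
  fl <- interpolate_1ms(c(0, 4), c(0.4, 0.4))
  expect_true(all(fl$value == 0.4))
  # already at 1 ms: identity
  id <- interpolate_1ms(0:10, sin(0:10))
  expect_equal(id$value, sin(0:10))
  # zero fill + flag outside the span
  zf <- interpolate_1ms(c(0, 4), c(1, 1), window = c(-2, 6))
  expect_equal(zf$value[zf$time_ms < 0], c(0, 0))
  expect_false(any(zf$observed[zf$time_ms < 0]))
  expect_error(interpolate_1ms(c(0, 4), c(1, 1), window = c(5, 2)), "empty")
})

test_that("peak locking aligns lag zero with the peak and zero-fills tails", {
  prof <- interpolate_1ms(seq(0, 1600, 4), pulse_shape(seq(0, 1600, 4),
                                                       400, 140, 0.8))
  pl <- peak_lock(prof, time_to_peak = 459)
  expect_equal(pl$value[pl$lag_ms == 0],
               prof$value[prof$time_ms == 459])
  late <- peak_lock(prof, time_to_peak = 1500)
  expect_true(all(late$value[late$lag_ms > 100] == 0))
  expect_false(any(late$observed[late$lag_ms > 100]))
})

test_that("relative profiles are scale invariant with unit peak", {
  tt <- seq(-500, 1600, by = 4)
  v <- pulse_shape(tt, 400, 140, 0.54)
  tr1 <- toy_trace(tt, v, rep(0, length(tt)))
  fe1 <- extract_features(tr1)
  c_scaled <- 3
  tr2 <- tr1; tr2$force_au <- tr2$force_au * c_scaled
  fe2 <- extract_features(tr2)
  expect_equal(fe2$pf, c_scaled * fe1$pf)
  expect_equal(fe2$response_key, fe1$response_key)
  prof1 <- relativize(interpolate_1ms(tt, v), fe1$pf)
  prof2 <- relativize(interpolate_1ms(tt, v * c_scaled), fe2$pf)
  expect_equal(prof1$value, prof2$value, tolerance = 1e-12)
  expect_equal(max(prof1$value), 1)
  expect_error(relativize(prof1, 0), "positive")
  # relative value: 0.25 at half the peak force
  half <- relativize(tibble::tibble(time_ms = 1:2, value = c(0.25, 0.5)), 0.5)
  expect_equal(half$value, c(0.5, 1))
})

test_that("time shifts move the timing features and nothing else", {
  tt <- seq(-500, 1600, by = 4)
  v <- pulse_shape(tt, 400, 140, 0.54)
  k <- 5  # samples
  v_shift <- c(rep(0, k), v[1:(length(v) - k)])
  fe <- extract_features(toy_trace(tt, v, rep(0, length(tt))))
  fes <- extract_features(toy_trace(tt, v_shift, rep(0, length(tt))))
  expect_equal(fes$rt, fe$rt + 4 * k)
  expect_equal(fes$onset_time, fe$onset_time + 4 * k)
  expect_equal(fes$offset_time, fe$offset_time + 4 * k)
  expect_equal(fes$time_to_peak, fe$time_to_peak + 4 * k)
  expect_equal(fes$rd, fe$rd)
  expect_equal(fes$pf, fe$pf)
})

test_that("AUC of simple geometries matches closed forms", {
  # triangle rising 0 to 1 over 100 ms then back: area 50 + 50
  lags <- -300:300
  tri <- tibble::tibble(lag_ms = lags,
                        value = pmax(0, 1 - abs(lags) / 100))
  a <- profile_auc(tri)
  expect_equal(a$auc_pre, 50, tolerance = 1e-9)
  expect_equal(a$auc_post, 50, tolerance = 1e-9)
  expect_equal(a$auc_total, 100, tolerance = 1e-9)
  zero <- profile_auc(tibble::tibble(lag_ms = lags, value = 0))
  expect_equal(unlist(zero), c(auc_pre = 0, auc_post = 0, auc_total = 0))
  # raised-cosine pulse: closed-form area known from the pulse integral
  on <- -80; w <- 160; A <- 1
  v <- pulse_shape(lags, on, w, A, pre_fraction = 0.5)
  rc <- profile_auc(tibble::tibble(lag_ms = lags, value = v))
  expect_equal(rc$auc_total, pulse_integral(on, w, A, 0.5), tolerance = 1e-6)
  expect_equal(rc$auc_total, rc$auc_pre + rc$auc_post, tolerance = 1e-9)
})

test_that("windowed mean forces reproduce a hand-computed toy", {
  prof <- tibble::tibble(time_ms = 0:500, value = 0:500 / 500)
  out <- windowed_mean_forces(prof, mean_matched_rt = 400)
  expect_equal(nrow(out), 5)
  # window '19-0' spans 381..400 -> mean of 381:400 / 500
  expect_equal(out$mean_force[out$window == "19-0"], mean(381:400) / 500)
  expect_equal(out$mean_force[out$window == "99-80"], mean(301:320) / 500)
  # constant profile: all windows equal
  cst <- windowed_mean_forces(tibble::tibble(time_ms = 0:500, value = 0.3), 400)
  expect_true(all(cst$mean_force == 0.3))
  expect_error(windowed_mean_forces(prof, 50), "before")
})

test_that("cell profiles average per participant cell and keep unit peaks", {
  eff <- effect_config(baseline_noise_sd = 0, baseline_level = 0)
  co <- simulate_cohort(cohort_config(n_participants = 2, n_blocks = 1), eff,
                        seed = 3)
  fe <- classify_outcomes(extract_features(co$forces), co$trials)
  fe <- fe[fe$outcome %in% c("correct", "commission") & !is.na(fe$pf), ]
  prof <- cell_profiles(co$forces, fe, lock = "peak", relative = TRUE)
  expect_true(all(c("participant_id", "outcome", "lag_ms", "value")
                  %in% names(prof)))
  # aggregated relative profile peaks at 1 when every trial peaks at lag 0
  peak_vals <- prof$value[prof$lag_ms == 0]
  expect_true(all(abs(peak_vals - 1) < 1e-9))
  # permuting trial order leaves the aggregate unchanged
  shuf <- fe[sample(nrow(fe)), ]
  prof2 <- cell_profiles(co$forces, shuf, lock = "peak", relative = TRUE)
  expect_equal(dplyr::arrange(prof, participant_id, outcome, lag_ms)$value,
               dplyr::arrange(prof2, participant_id, outcome, lag_ms)$value)
})
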