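test_that("greedy matching follows the registered tie-breaking rules", {
  # tie on |RT difference|: prefer the correct trial closer in trial number
  fe <- dplyr::bind_rows(
    toy_features(1L, 5L, "commission", rt = 300),
    toy_features(1L, 3L, "correct", rt = 295),
    toy_features(1L, 8L, "correct", rt = 305))
  m <- greedy_match(fe, "rt")
  expect_equal(m$correct_trial, 3L)  # |5-3| = 2 beats |8-5| = 3
  expect_equal(m$delta, -5)
  # tie also on trial distance: smaller trial number wins
  fe2 <- dplyr::bind_rows(
    toy_features(1L, 5L, "commission", rt = 300),
    toy_features(1L, 3L, "correct", rt = 295),
    toy_features(1L, 7L, "correct", rt = 305))
  expect_equal(greedy_match(fe2, "rt")$correct_trial, 3L)
  # single error, single correct: that pair
  fe3 <- dplyr::bind_rows(
    toy_features(2L, 1L, "commission", rt = 500),
    toy_features(2L, 9L, "correct", rt = 100))
  m3 <- greedy_match(fe3, "rt")
  expect_equal(nrow(m3), 1)
  expect_equal(m3$correct_trial, 9L)
  # more errors than corrects cannot complete
  fe4 <- dplyr::bind_rows(
    toy_features(1L, 1L, "commission", rt = 1),
    toy_features(1L, 2L, "commission", rt = 2),
    toy_features(1L, 3L, "correct", rt = 3))
  expect_error(greedy_match(fe4, "rt"), "cannot complete")
})

test_that("greedy matcher equals the exhaustive-scan oracle", {
  set.seed(99)
  for (rep in 1:120) {
    n_err <- sample(1:8, 1)
    n_cor <- sample(n_err:12, 1)
    ids <- sample(1:60, n_err + n_cor)
    vals <- round(stats::rnorm(n_err + n_cor, 400, 40),
                  sample(c(0, 1), 1))  # ties likely at 0 decimals
    fe <- tibble::tibble(
      participant_id = 1L,
      trial_global = ids,
      outcome = factor(rep(c("commission", "correct"), c(n_err, n_cor)),
                       levels = levels(toy_features(1, 1, "correct", 1)$outcome)),
      rt = vals, pf = vals / 1000)
    got <- greedy_match(fe, "rt")
    want <- oracle_match(fe[fe$outcome == "commission", ],
                         fe[fe$outcome == "correct", ], "rt")
    expect_identical(got$error_trial, want$error_trial)
    expect_identical(got$correct_trial, want$correct_trial)
    # injectivity and completeness
    expect_equal(anyDuplicated(got$correct_trial), 0)
    expect_setequal(got$error_trial,
                    fe$trial_global[fe$outcome == "commission"])
  }
})

test_that("TOST behaves at its boundary cases", {
  mk <- function(deltas) {
    tibble::tibble(participant_id = seq_along(deltas), delta = deltas)
  }
  # all differences zero: both one-tailed tests significant, pass
  z <- equivalence_test(mk(rep(0, 34)), bound = 2)
  expect_true(z$pass)
  expect_true(z$zero_variance)
  # all differences on the boundary: upper t = 0, fail
  b <- equivalence_test(mk(rep(2, 34)), bound = 2)
  expect_false(b$pass)
  expect_equal(b$t_upper, 0)
  expect_equal(length(b$offenders), 34L)
  # tight distribution well inside the bounds passes essentially always
  set.seed(11)
  passes <- vapply(1:50, function(i) {
    equivalence_test(mk(rnorm(34, 0, 0.5)), bound = 2)$pass
  }, TRUE)
  expect_gte(mean(passes), 0.98)
  # offenders use weak inequalities
  off <- equivalence_test(mk(c(rep(0, 20), 2)), bound = 2)
  expect_equal(off$offenders, 21L)
})

test_that("reported TOST statistic is the smaller absolute t", {
  set.seed(2)
  m <- tibble::tibble(participant_id = 1:20, delta = rnorm(20, 0.5, 1))
  eq <- equivalence_test(m, bound = 2)
  expect_equal(eq$t_reported,
               if (abs(eq$t_lower) <= abs(eq$t_upper)) eq$t_lower else eq$t_upper)
})

test_that("an already-passing match needs zero trim iterations", {
  set.seed(4)
  fe <- dplyr::bind_rows(lapply(1:20, function(p) {
    rts <- rnorm(40, 400, 30)
    dplyr::bind_rows(
      toy_features(p, 1:12 * 2L, "commission", rt = rnorm(12, 400, 30)),
      toy_features(p, 100L + 1:28, "correct", rt = rnorm(28, 400, 30)))
  }))
  out <- trim_and_rematch(fe, "rt", bound = 2)
  expect_true(out$converged)
  expect_equal(out$iterations, 0)
  expect_equal(nrow(out$log), 1)
  expect_identical(out$match, greedy_match(fe, "rt"))
})

test_that("systematic offenders get their fastest errors trimmed first", {
  set.seed(8)
  ok <- dplyr::bind_rows(lapply(1:12, function(p) {
    dplyr::bind_rows(
      toy_features(p, 1:15 * 3L, "commission", rt = rnorm(15, 400, 5)),
      toy_features(p, 200L + 1:60, "correct", rt = rnorm(60, 400, 5)))
  }))
  # participant 13: every error RT far below every correct RT
  bad <- dplyr::bind_rows(
    toy_features(13L, 1:15 * 3L, "commission", rt = seq(300, 330, length.out = 15)),
    toy_features(13L, 200L + 1:60, "correct", rt = rnorm(60, 400, 5)))
  fe <- dplyr::bind_rows(ok, bad)
  first <- equivalence_test(greedy_match(fe, "rt"), bound = 2)
  expect_true(13L %in% first$offenders)
  out <- trim_and_rematch(fe, "rt", bound = 2, max_iter = 10)
  expect_gte(out$iterations, 1)
  # trimmed ids belong to participant 13's slowest-to-match (smallest RT) errors
  expect_true(all(out$trimmed %in% (1:15 * 3L)))
  trimmed_rts <- seq(300, 330, length.out = 15)[match(sort(out$trimmed),
                                                      1:15 * 3L)]
  expect_equal(sort(out$trimmed),
               (1:15 * 3L)[order(seq(300, 330, length.out = 15))][
                 seq_along(out$trimmed)])
  # flags instead of trimming below the observation floor
  floor_out <- trim_and_rematch(fe, "rt", bound = 2, min_obs = 15)
  expect_true(13L %in% floor_out$flagged)
})

test_that("matched pairs are a subset of surviving trials, corrects unique", {
  co <- simulate_cohort(cohort_config(n_participants = 6, n_blocks = 6),
                        seed = 17, emit = "features")
  sel <- select_trials(co$features, co$trials)
  for (v in c("rt", "pf")) {
    m <- greedy_match(sel, v)
    expect_equal(anyDuplicated(paste(m$participant_id, m$correct_trial)), 0)
    err_ids <- paste(sel$participant_id, sel$trial_global)[
      sel$outcome == "commission"]
    expect_true(all(paste(m$participant_id, m$error_trial) %in% err_ids))
  }
})

test_that("matched PF means agree to two decimals on a passing PF match", {
  # full-length sessions: the correct pool is dense enough for
  # nearest-neighbour matching to null the mean PF difference
  co <- simulate_cohort(cohort_config(n_participants = 10, n_blocks = 17),
                        seed = 23, emit = "features")
  sel <- select_trials(co$features, co$trials)
  out <- trim_and_rematch(sel, "pf", bound = 0.05)
  expect_true(out$converged)
  expect_equal(round(mean(out$match$error_value), 2),
               round(mean(out$match$correct_value), 2))
})
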