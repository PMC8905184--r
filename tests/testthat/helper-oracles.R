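# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive re-implementation of the matching rules by direct scanning:
# visit error trials in ascending trial number, score every unmatched
# correct trial by (|value diff|, |trial-number diff|, trial number) and
# take the lexicographic minimum.
oracle_match <- function(errors, corrects, variable) {
  errors <- errors[order(errors$trial_global), ]
  avail <- rep(TRUE, nrow(corrects))
  pairs <- list()
  for (i in seq_len(nrow(errors))) {
    best <- NULL; best_key <- NULL
    for (j in which(avail)) {
      key <- c(abs(corrects[[variable]][j] - errors[[variable]][i]),
               abs(corrects$trial_global[j] - errors$trial_global[i]),
               corrects$trial_global[j])
      if (is.null(best_key) ||
          key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] < best_key[3])) {
        best <- j; best_key <- key
      }
    }
    avail[best] <- FALSE
    pairs[[i]] <- data.frame(error_trial = errors$trial_global[i],
                             correct_trial = corrects$trial_global[best])
  }
  do.call(rbind, pairs)
}

# JZS Bayes factor by dense quadrature over the effect size directly:
# noncentral-t likelihood averaged over a Cauchy prior.
oracle_jzs <- function(t, n, scale = 1) {
  f <- function(delta) {
    suppressWarnings(stats::dt(t, n - 1, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, scale)
  }
  num <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  num / stats::dt(t, n - 1)
}

# Crossing times by explicit interpolation to a 1-ms grid followed by a
# scan (the definitional route the fast closed-form path must match).
oracle_crossings <- function(times, values, thr) {
  grid <- seq(min(times), max(times), by = 1)
  v <- stats::approx(times, values, xout = grid)$y
  hit <- which(v >= thr)
  if (!length(hit)) return(c(NA_real_, NA_real_))
  c(grid[hit[1]], grid[hit[length(hit)]])
}

# A single synthetic trial's two-channel trace in the long format.
toy_trace <- function(times, left, right, participant_id = 1L,
                      trial_global = 1L, block = 1L, trial_in_block = 2L) {
  tibble::tibble(
    participant_id = participant_id, block = block,
    trial_in_block = trial_in_block, trial_global = trial_global,
    channel = rep(c("left", "right"), each = length(times)),
    sample_idx = rep(seq_along(times) - 1L, 2L),
    time_ms_from_target = rep(times, 2L),
    force_au = c(left, right))
}

# Trial metadata matching toy_trace defaults.
toy_meta <- function(participant_id = 1L, trial_global = 1L,
                     correct_key = "left", block = 1L,
                     trial_in_block = 2L) {
  tibble::tibble(participant_id = participant_id, block = block,
                 trial_in_block = trial_in_block,
                 trial_global = trial_global, is_practice = FALSE,
                 target_letter = "T", distractor_letter = "O",
                 correct_key = correct_key,
                 response_key_online = correct_key,
                 online_outcome = "correct")
}

# Feature rows for matching tests without any traces.
toy_features <- function(participant_id, trial_global, outcome, rt,
                         pf = 0.5) {
  tibble::tibble(
    participant_id = participant_id, trial_global = trial_global,
    outcome = factor(outcome,
                     levels = c("correct", "commission", "omission",
                                "anticipatory", "miscellaneous")),
    rt = rt, pf = pf)
}
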