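#' Raised-cosine force pulse
#'
#' Evaluates the canonical force pulse used by the synthetic cohort
#' generator: two half-cosines (rise and fall) joined at the peak. The
#' pulse is parameterised directly by the quantities the analysis
#' extracts -- the time at which it crosses the response threshold on the
#' way up (`onset`), the time between the upward and downward threshold
#' crossings (`width`), and the maximum force (`amplitude`) -- so that
#' ground truth for response time, response duration and peak force is
#' available in closed form.
#'
#' The pulse is continuous, unimodal and zero outside a finite support.
#' It equals `threshold` exactly at `onset` and `onset + width`, and
#' attains `amplitude` at `onset + pre_fraction * width`.
#'
#' @param t Numeric vector of times (ms) at which to evaluate the pulse.
#' @param onset Time (ms) of the upward threshold crossing.
#' @param width Duration (ms) between upward and downward crossings.
#'   Must be positive.
#' @param amplitude Peak force (a.u.). Must exceed `threshold`.
#' @param pre_fraction Fraction of `width` spent before the peak,
#'   strictly between 0 and 1.
#' @param threshold Force level (a.u.) defining the crossings; defaults
#'   to the 0.25 a.u. response-registration threshold.
#' @return Numeric vector of forces (a.u.), same length as `t`.
#' @examples
#' pulse_shape(400, onset = 400, width = 140, amplitude = 0.54)  # 0.25
#' @export
pulse_shape <- function(t, onset, width, amplitude, pre_fraction = 55 / 130,
                        threshold = 0.25) {
  stopifnot(width > 0, pre_fraction > 0, pre_fraction < 1, threshold > 0)
  if (amplitude <= threshold) {
    rlang::abort("`amplitude` must exceed `threshold` for a supra-threshold pulse.")
  }
  sup <- pulse_support(onset, width, amplitude, pre_fraction, threshold)
  peak <- onset + pre_fraction * width
  out <- numeric(length(t))
  rise <- t >= sup[["start"]] & t <= peak
  fall <- t > peak & t <= sup[["end"]]
  R <- peak - sup[["start"]]
  F_ <- sup[["end"]] - peak
  out[rise] <- amplitude / 2 * (1 - cos(pi * (t[rise] - sup[["start"]]) / R))
  out[fall] <- amplitude / 2 * (1 + cos(pi * (t[fall] - peak) / F_))
  out
}

#' Support and integral of the raised-cosine pulse
#'
#' `pulse_support()` returns the start and end of the non-zero support;
#' `pulse_integral()` the closed-form area under the pulse, used as the
#' analytic reference for numerical integration of force profiles.
#'
#' @inheritParams pulse_shape
#' @return `pulse_support()`: named numeric `c(start, end)` (ms);
#'   `pulse_integral()`: scalar area (a.u. x ms).
#' @export
pulse_support <- function(onset, width, amplitude, pre_fraction = 55 / 130,
                          threshold = 0.25) {
  stopifnot(amplitude > threshold)
  # fraction of the rise spent below threshold: A/2 (1 - cos(pi q)) = thr
  q <- acos(1 - 2 * threshold / amplitude) / pi
  # fraction of the fall spent above threshold: A/2 (1 + cos(pi p)) = thr
  p <- acos(2 * threshold / amplitude - 1) / pi
  rise <- pre_fraction * width / (1 - q)
  fall <- (1 - pre_fraction) * width / p
  peak <- onset + pre_fraction * width
  c(start = peak - rise, end = peak + fall)
}

#' @rdname pulse_support
#' @export
pulse_integral <- function(onset, width, amplitude, pre_fraction = 55 / 130,
                           threshold = 0.25) {
  sup <- pulse_support(onset, width, amplitude, pre_fraction, threshold)
  peak <- onset + pre_fraction * width
  amplitude / 2 * ((peak - sup[["start"]]) + (sup[["end"]] - peak))
}
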