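---
title: "Methods: response-force analysis of error cancellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-force analysis of error cancellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the measurement model

When people commit an action slip on a speeded choice task, do they
merely register the error after the fact, or do they actively cancel
the erroneous movement while it is still unfolding? With isometric
force keys the full time course of every keypress is observable: a
response is registered when the force on one key exceeds a threshold of
0.25 a.u. (about 2.5 N) above baseline, and the complete force profile
is recorded at 250 Hz from fixation onset until well into the
inter-trial interval. Three derived quantities carry the argument:

* **RT** (response time): target onset to the first threshold crossing;
* **RD** (response duration): first to last threshold crossing within
  the trial, split at the first occurrence of the peak into pre-peak
  and post-peak epochs;
* **PF** (peak force): the maximum baseline-corrected force.

Active cancellation predicts shorter RDs for commission errors than for
correct responses. Because errors also tend to start earlier (shorter
RT) and peak lower (smaller PF), and either difference could shorten RD
for purely biomechanical reasons, the inference rests on comparing
error and correct trials *after* matching them pairwise on RT and on
PF. `keyforce` implements that full chain: feature extraction, the
exclusion cascade, the matching algorithm with equivalence-driven
trimming, the inferential toolbox, and a synthetic cohort generator
with exported ground truth so that every stage can be tested against
known parameters.

## Feature extraction

Traces are baseline-corrected per trial and channel by subtracting the
mean of the first 10 samples recorded at or after target onset;
correction-induced negative values are clamped to zero because true
negative forces cannot occur on this apparatus. All timing features are
defined on a 1-ms linear interpolation of the 4-ms samples: the onset
is the first millisecond at which the interpolated force reaches the
threshold, the offset the last such millisecond anywhere in the trial
(a dip below threshold between two supra-threshold lobes is therefore
spanned — the offset is defined by the *last* crossing). The responding
channel is the first channel to cross; ties at identical onset times
resolve to the left key. Time-to-peak is the first occurrence of the
maximum, so force plateaus resolve to their leading edge, and
`rd == rd_pre_peak + rd_post_peak` holds exactly by construction.
`extract_features()` computes the crossings in closed form from the
4-ms samples; the tests verify its equality with an explicit
interpolate-then-scan oracle. The 1-ms grid quantizes each crossing
inward, so latent onsets are recovered to at most 1 ms (plus a chord
error orders of magnitude below one step) and latent durations to at
most 2 ms.

Covert responses — activity on the unpressed key that reaches 0.1 a.u.
but not the 0.25 a.u. response threshold — are flagged per trial from
the same baseline-corrected traces.

Two baselines exist in the chain: online response registration uses the
first 10 samples from *fixation* onset, while all offline features use
the first 10 samples from *target* onset. The package applies each in
its own role.

## Profiles and areas under the curve

For profile analyses each trial's responding-channel trace is
interpolated to 1 ms, windowed either target-locked (0–1600 ms) or
peak-locked (−300 to +300 ms around the first PF occurrence; lags
outside the recording are zero-filled and flagged), and optionally
rescaled to fractions of that trial's PF (relative profiles are
computed per trial *before* averaging; the alternative order is not
distinguishable from published values, and per-trial scaling keeps the
lag-0 value exactly 1). Cell means are pointwise averages across trials
within participant × accuracy; grand means average participant means.

AUCs integrate the aggregated relative profile by the trapezoid rule
over the pre-peak (−300..0) and post-peak (0..+300) halves of the
peak-locked window, in units of fraction × ms. The full half-windows
are used rather than onset-to-offset spans: the baseline is ≈ 0 outside
the response, and the printed AUC magnitudes are only consistent with
integration on the peak-locked window in fraction scale. At 1-ms
resolution the trapezoid rule is exact for the piecewise-linear
interpolated profiles.

The windowed follow-up analysis averages absolute target-locked force
in five 20-ms windows counting backwards from the mean RT of the
RT-matched data ("99–80" down to "19–0" ms before it).

## Trial selection

The cascade removes, in order: the practice block; the first trial of
each block; trials whose immediately preceding trial (in the original
chronology, including trials later removed for other reasons) was not
correct; anticipatory responses (threshold crossings during fixation)
and omissions (no supra-threshold response anywhere in the trial). A
single outlier pass then removes trials whose RT, RD or PF deviates
more than 2.5 s.d. from the participant × accuracy cell mean — one
pass, not iterated, because a single removal fraction is the reported
behaviour of such screens; cells with fewer than two trials are left
alone. Participants are excluded when they responded correctly on less
than 60% of experimental trials (percentage base: all non-practice,
non-first-of-block trials before sequence filtering) or when fewer
than 10 trials remain in either accuracy cell; both thresholds are
strict inequalities. The preceding-trial verdict is stored on first
evaluation, which makes the cascade idempotent.

## Matching, equivalence, trimming

`greedy_match()` pairs error trials with correct trials within
participant: error trials are visited in ascending trial number, each
taking the still-unmatched correct trial with the smallest absolute
difference in the match variable (RT or PF). Ties break first by the
smallest trial-number distance, then by the smaller trial number.
Matched corrects become unavailable, so the pairing is injective and
deliberately order-dependent — the algorithm is specified procedurally
and fidelity beats global optimality. The test suite proves equality
with an exhaustive scan on hundreds of randomized small problems.

Matching success is assessed by TOST equivalence tests on the
participant-level mean differences (correct − error): one-tailed
one-sample t-tests against −2/+2 ms for RT or −0.05/+0.05 a.u. for PF,
both required significant at α = 0.05 (one-tailed each; the global α,
as no separate TOST level is specified). The reported statistic is the
one with the smaller |t|. If participants sit at or beyond a bound
(weak inequalities), the bottom 5% of *their* error trials (smallest
values of the match variable, at least one trial, rounded up) are
removed and matching re-runs; if nobody offends but the TOST still
fails, the bottom 5% is trimmed for all participants. Trims accumulate
across iterations (previously trimmed trials are not re-included — the
procedure reads as monotone shrinkage). The loop stops on a pass, after
`max_iter` (default 20; termination is implied but unbounded in the
registered description), or when a participant would fall below 10
error trials, in which case they are flagged and the pipeline excludes
them from all datasets and re-matches.

## Inferential toolbox

* `paired_t()` reports t, one- or two-tailed p, Cohen's dz
  (= t/√n), and the CI of the mean paired difference; one-tailed CIs
  have a single finite bound.
* `rm_anova()` is a fully within-subject ANOVA on subject × cell means
  (one or two factors), each effect tested against its own
  subject-by-effect stratum, with partial η² = SS_eff/(SS_eff +
  SS_err). For effects with more than 1 numerator df it reports the
  Greenhouse–Geisser ε from the orthonormalized contrast covariance,
  the corrected p, and Mauchly's test; the "if necessary" trigger for
  reporting the corrected p is Mauchly p < 0.05. The implementation is
  cross-checked against `car::Anova` in the tests.
* `ntiles()` reproduces rank-based quantile binning with ties to the
  lower bin. The pilot-style distributional analysis computes RT
  quartiles within participant × accuracy (the natural reading; a
  pooled-within-participant alternative is a documented switch for
  users who prefer it).
* `bayes_t_paired()` is the JZS paired t-test (Cauchy scale 1 by
  default), evaluated by adaptive quadrature of the g-mixture integral
  at a declared 1e-6 relative tolerance; the tests compare it against
  an independent dense quadrature of the noncentral-t × Cauchy form on
  a (t, n) grid.
* `bayes_correlation()` uses the exact sampling density of r with a
  stretched beta prior (width 1/3 by default), one-sided priors
  renormalized to the half-line; it agrees with the JASP-style default
  correlation Bayes factor to four digits.
* `ci_dz()` inverts the noncentral t distribution (root finding at
  1e-8) for the CI of a standardized paired effect.
* `solve_power_paired_t()` solves the continuous noncentral-t power
  equation. Planned sample sizes are conventionally quoted by rounding
  that continuous solution to the nearest integer, and that is the
  default; `rounding = "ceiling"` returns the smallest n whose power
  actually reaches the target (the two differ, e.g. 23 vs 24 at
  dz = 0.93 and 99% power, because power at n = 23 is 0.9892).
* `solve_power_correlation()` exposes two approximations: the
  t-critical-value/Fisher-z hybrid used by the widely-cited `pwr`
  routine (default; yields n = 11 for r = 0.81 at 95% one-tailed
  power) and the plain Fisher-z bound (yields 12).

## The registered decision tree

`run_pipeline()` builds three datasets — unmatched, RT-matched,
PF-matched — and walks the registered hypothesis chain: 2×2
accuracy × time-window ANOVAs on RD per dataset with conditional
one-tailed follow-ups; the same on AUCs; the 5×2 windowed-force ANOVA
gated on significant pre-peak AUC effects in all three datasets; the
one-tailed correlation between ΔAUC (unmatched total AUC, correct −
error) and the covert-response rate, with a Bayesian fallback when not
significant; and one-tailed RT and PF validation tests. "Active
cancellation" is inferred only when errors show shorter RDs in all
three datasets; otherwise the Bayesian fallback computes JZS Bayes
factors per dataset and reports the sequential-sampling trajectory
(BF01 after each increment of two participants) over the participants
already available — the stopping rule is implemented, recruitment is
not. `decide_hypotheses()` maps test outcomes to interpretation labels
deterministically and is exercised against a hand-coded truth table of
fabricated outcome combinations.

## The synthetic cohort generator

`simulate_cohort()` emulates the experiment that the analysis chain
assumes: a 32-trial practice block plus 17 blocks of 64 trials, four
target letters with a 4:2 letter-to-key mapping counterbalanced across
participants, eight distractor letters, 500 ms fixation, 600 ms
response deadline, and two force channels sampled every 4 ms from
fixation onset through 1600 ms after target onset.

Every registered response is a raised-cosine pulse — rise and fall
half-cosines joined at the peak — parameterised directly by its
threshold-crossing times and maximum, so the latent RT, RD and PF of
each trial are exact closed-form properties of the trace
(`pulse_shape()`, `pulse_integral()`). No published description of the
force shape exists; any smooth unimodal family would do, and this one
was chosen because its ground truth is analytic. The pre-peak fraction
defaults to 55/130, the ratio of the reported pre- and post-peak
duration means, which is an extrapolation from two printed numbers, not
a measured shape statistic.

Accuracy effects are injected at the latent level: participant means
for correct trials are drawn from truncated normal distributions, and
each participant's error means subtract a heterogeneous effect
(defaults 13 ms RT, 30 ms RD, 0.11 a.u. PF, with between-participant
effect s.d.s of 10 ms, 10 ms and 0.07 a.u.). Those location defaults
are the unmatched condition means reported for this paradigm
(449/436 ms, 145/115 ms, 0.54/0.43 a.u.), and the heterogeneity values
are set so that the implied paired effect sizes land near the reported
dz values. Trial-level durations are drawn from a lognormal with the
participant's latent mean — strictly positive and right-skewed, as
duration distributions are, and with the injected mean reproduced
exactly, which keeps parameter recovery unbiased. Peak forces use a
truncated normal above 0.27 a.u. (a registered response must exceed the
0.25 a.u. threshold; reported PF means are necessarily means of
supra-threshold responses). The trial-to-trial PF s.d. defaults to
0.18 a.u.: combined with the effect heterogeneity this reproduces the
reported paired PF effect size (dz ≈ 1.05) and the empirical
observation that PF matching succeeds essentially immediately, which
requires substantial within-participant overlap between error and
correct force distributions.

Commission errors occur at a participant-level rate of mean 9.4%
(s.d. 5.6%, truncated) — the reported sample descriptives; the
generator needs an error rate and none is otherwise specified.
Omissions occur at 9.8%, anticipations at 0.1%, and correct trials
carry covert sub-threshold pulses on the other key (amplitude uniform
in [0.1, 0.25) a.u.) at a participant-level rate of mean 3.11%
(s.d. 4.07%, truncated at zero). Pre-error speeding exists as an
optional RT modulation and defaults to off: the selection cascade
excludes post-error trials anyway, so it matters only for filter
tests.

`emit = "features"` skips trace rendering and returns the idealised
per-trial features directly; the trace → feature map is validated
separately by noise-free round-trip tests, so large simulation studies
of the selection, matching and inference stages can run at feature
level without re-rendering millions of samples.

What the generator deliberately does *not* emulate: visual stimuli
(letters are metadata), feedback effects on subsequent behaviour,
serial dependence beyond the optional pre-error speeding, skewed RT
distributions (RTs are truncated normal), drifts or low-frequency
noise in the force sensors, and any correlation between error rate and
effect sizes across participants. Passing recovery tests on these
cohorts therefore demonstrates that the pipeline measures what it
claims under the stated statistical structure — not that real force
data satisfy that structure.

## Numerical choices

* Linear interpolation at 1 ms everywhere; crossing times computed in
  closed form but defined by the 1-ms grid semantics (first/last grid
  point at or above threshold).
* Trapezoid rule for AUCs (exact for piecewise-linear profiles).
* Ties for the maximum resolve to the first occurrence; responding-
  channel ties resolve to the left key.
* Quadrature tolerance 1e-6 (Bayes factors), root finding 1e-8 (power,
  noncentral-t CIs).
* Zero-variance difference vectors yield flagged infinite-t results
  rather than errors mid-pipeline; exact-boundary TOST cases report
  t = 0 and fail equivalence.
* The offset search runs over the full recorded trial including the
  inter-trial window, matching the "last time in a trial" reading.
* Equivalence trimming accumulates (trimmed trials are never
  re-included in later iterations).

## Problem sizes in the test suite

The packaged tests run cohorts of 34 simulated participants with 6
experimental blocks for the recovery and calibration studies (200
cohorts at the study's effect sizes, 200 under a null generator with
all accuracy effects removed), 100 full-length 17-block cohorts for
the matching-behaviour study, and small traced cohorts (2–12
participants, 1–4 blocks) wherever raw traces are rendered. These
sizes are the package's choice of test design: effect and noise
parameters are never scaled, only the number of trials and cohorts
over which they are evaluated.

## Known limitations

The RT-matched and PF-matched datasets inherit the greedy matcher's
order dependence; a globally optimal assignment would change individual
pairs (not the aggregate behaviour tested here) and is out of scope by
design. The Bayesian sequential-sampling rule is reported as a
trajectory over available data only. Pilot-format (discrete keyboard)
data are supported at the feature level — the `miscellaneous` outcome
class exists for them — but no keyboard event parser is included.
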