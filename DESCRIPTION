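Package: keyforce
Title: Response-Force Profile Analysis for Error Cancellation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-channel isometric response-force
    recordings from speeded choice tasks, built around the question of
    whether commission errors are actively cancelled while the keypress
    unfolds. Extracts response onset, offset, duration, peak force and
    peak-locked force profiles from raw traces; classifies trial outcomes
    and applies the standard exclusion cascade; pairs error trials with
    correct trials by response time or peak force using a greedy
    nearest-neighbour algorithm with TOST equivalence checks and an
    iterative trimming loop; and runs the registered inference chain
    (repeated-measures ANOVAs with Greenhouse-Geisser correction, paired
    effect sizes with noncentral-t confidence intervals, JZS and
    stretched-beta Bayes factors, power solvers). A synthetic cohort
    generator with exported ground truth supports calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    car,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
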