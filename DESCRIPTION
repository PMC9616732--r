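Package: spindletopo
Title: Sleep Spindle and Slow-Oscillation Topography Analysis for Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the scalp topography of sleep spindles and
    slow oscillations relates to prior waking activity. Implements amplitude-
    criterion detection of fast spindles (12-15 Hz) and slow oscillations
    (0.3-1.25 Hz) during NREM sleep, wake oscillatory-power contrasts with a
    cluster-based permutation test over channel-by-frequency maps,
    slow-oscillation phase coupling of spindles, participant-level Spearman
    overlap between wake and sleep topographies, and the group statistics
    (repeated-measures ANOVA, Holm-corrected post-hoc tests, partial rank
    correlations, and topography-shuffling permutation nulls against
    behaviour). A synthetic-cohort generator with full ground truth supports
    calibration and parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse,
    knitr
Config/testthat/edition: 3
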