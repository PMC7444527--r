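Package: matchbias
Title: Signal Detection Analysis of Face Matching Under Prior Identity Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing graded human face-matching judgements made in
    the presence of prior identity labels ("same person" / "different people")
    attributed to a human or computer source. Implements the rating-task signal
    detection workflow: threshold-sweep true/false positive rates and accuracy,
    pooled d-prime and decision criterion, Gaussian-assumption ROC fits in
    z-space with the Az area statistic, volunteer-level bootstrap confidence
    intervals, per-item rank tests and mean-shift summaries, chi-squared
    homogeneity checks, and one-way and repeated-measures ANOVA layouts.
    Includes a synthetic rater generator (equal-variance Gaussian observers
    with ordered category boundaries and a label-induced criterion shift) that
    emulates the nested survey design, so the full pipeline and its
    parameter-recovery properties can be exercised without access to raw
    human-subjects data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
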