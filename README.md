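# matchbias

Signal detection analysis of human face matching under prior identity
labels.

## The problem

In identity-verification workflows, people routinely review face-matching
decisions made by algorithms (or by other people): a reviewer sees two face
photographs together with a prior "same person" / "different people" label
and renders their own judgement. Does the label degrade the reviewer's
ability to *discriminate* faces, or does it *bias* their decision while
leaving discriminability intact? The distinction matters: a biased reviewer
will tend to ratify whatever the algorithm said, which bounds the accuracy
a human–algorithm team can reach.

`matchbias` is for researchers analysing graded face-matching judgements
from nested survey designs: volunteers rate face pairs on a 7-point
certainty scale (−3 "absolutely certain different" … +3 "absolutely certain
same"), in a control arm with no labels or in sourced arms where each pair
carries a prior label, counterbalanced across survey versions so every pair
appears under both labels.

## The model

Under the equal-variance Gaussian observer model, a face comparison
generates latent similarity evidence: N(d′, 1) for mated pairs, N(0, 1) for
non-mated pairs. Sliding a threshold θ over the rating scale gives per
threshold

    TPR_θ = (1/n) Σ_same  [R_i > θ]
    FPR_θ = (1/m) Σ_diff  [R_i > θ]
    ACC_θ = (n·TPR_θ + m·(1 − FPR_θ)) / (n + m)

and from one operating point

    d′ = z(TPR) − z(FPR)          (sensitivity)
    c  = −(z(TPR) + z(FPR)) / 2   (decision criterion)

with z = Φ⁻¹. Across the grid, OLS of z(TPR) on z(FPR) gives intercept I
and slope S, and the Gaussian-assumption area under the ROC is
Az = Φ(I / √(1 + S²)) — a threshold-free sensitivity measure. A label that
merely biases the observer moves c (and slides the operating point along
the ROC); a label that harms attention would lower d′ and Az.

The package implements the full workflow: response-table validation and
catch-trial screening, threshold sweeps, pooled d′/criterion, z-space ROC
fits, volunteer-level bootstrap CIs, per-item rank tests with an
across-item mean-shift summary, χ² homogeneity tests, one-way and
repeated-measures ANOVA — plus a synthetic rater generator (Gaussian
observers with ordered category boundaries and a label-induced criterion
shift δ) that emulates the survey design for testing and parameter
recovery.

## Worked example

```r
library(matchbias)

records <- simulate_survey(simulate_raters(sim_config(seed = 42)))
report  <- run_full_analysis(records, config = analysis_config(
  bootstrap = bootstrap_config(B = 2000, seed = 5)), quiet = TRUE)
report$sdt
#> # A tibble: 3 × 8
#>   condition     n dprime dprime_lower dprime_upper criterion criterion_lower criterion_upper
#>   <chr>     <int>  <dbl>        <dbl>        <dbl>     <dbl>           <dbl>           <dbl>
#> 1 none        120   1.33         1.18         1.48     0.203          0.127            0.275
#> 2 same        238   1.35         1.21         1.50     0.161          0.0902           0.238
#> 3 different   238   1.33         1.18         1.49     0.327          0.251            0.403
```

Read: the d′ intervals of the three conditions overlap (labels did not
change discriminability), while the criterion under "different" labels
(0.33) sits clearly above the criterion under "same" labels (0.16) — the
gap ≈ 0.17 here estimates the generating shift δ = 0.22 up to sampling
noise. `report$roc_fits` shows the same story threshold-free: the three
conditions' fitted Az values (0.826, 0.826, 0.816) agree to about 0.01.

A small deterministic fixture ships with the package:

```r
responses <- read_response_table(
  system.file("extdata", "synthetic_responses.csv", package = "matchbias"))
screened <- screen_catch_trials(responses)   # excludes the planted failure
threshold_sweep(screened$kept)
```

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on
synthetic data and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # survey + volunteer profiles + ground truth
Rscript analysis/02_screen.R     # catch-trial screening, design summary
Rscript analysis/03_analyze.R    # rates, ANOVA, SDT, ROC, item tests -> results/report/
Rscript analysis/04_recovery.R   # parameter recovery across replicate surveys
```

Stage 3 prints, among other things, the pooled SDT table with bootstrap
CIs, the fitted Az per condition with their maximum pairwise difference,
and the across-item mean shift with its t test; stage 4 reports how the
pooled estimators concentrate on the generating (d′, δ) over 40 replicate
surveys.

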