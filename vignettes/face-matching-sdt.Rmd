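---
title: "Signal detection analysis of face matching under prior identity labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection analysis of face matching under prior identity labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchbias)
```

## The problem

When people verify identities by comparing two face photographs, they are
often shown a prior decision — a "same person" or "different people" label
attributed to a computer algorithm or to another human. `matchbias`
implements the statistical workflow for asking what such labels do to the
human judgement: do they degrade the observer's ability to *discriminate*
faces (as an attention account would predict), or do they *bias* the
decision without touching discriminability?

Signal detection theory (SDT) separates the two. Each face-pair comparison
generates latent similarity evidence; under the equal-variance Gaussian
model, evidence is N(d′, 1) for mated pairs and N(0, 1) for non-mated
pairs. The observer reports a graded certainty rating on a 7-point scale
(−3 "absolutely certain different" … +3 "absolutely certain same") by
comparing the evidence to six ordered category boundaries. Sliding a
decision threshold θ across the scale turns ratings into binary decisions
and yields, per threshold,

- TPR_θ = fraction of mated pairs rated above θ,
- FPR_θ = fraction of non-mated pairs rated above θ,
- ACC_θ = (n·TPR_θ + m·(1 − FPR_θ)) / (n + m) for n mated and m non-mated
  trials — an identity that holds exactly for every rate table the package
  produces.

From a single operating point, sensitivity and criterion are

- d′ = z(TPR) − z(FPR),
- c = −(z(TPR) + z(FPR)) / 2,

with z the standard normal quantile function. The criterion formula is the
standard equal-variance one; applied to the published pooled rates it
reproduces the reported criteria to the printed precision (0.72/0.25 →
0.046 ≈ 0.05; 0.66/0.17 → 0.271 ≈ 0.27), which is how we validated the
choice — the source tables print criteria without stating the formula.

Across the whole grid, the ROC is summarised by a line in z-space:
ordinary least squares of z(TPR) on z(FPR) gives intercept I and slope S,
and the area under the Gaussian-assumption ROC is Az = Φ(I / √(1 + S²)).
For an equal-variance observer the line has S = 1, I = d′, and
Az = Φ(d′/√2). We regress z(TPR) on z(FPR) (not errors-in-variables),
matching how the fit is conventionally described; both axes carry sampling
noise, so the fitted slope is mildly attenuated, identically so across
conditions being compared.

## Pooling, degenerate rates, and corrections

With only 6 mated and 6 non-mated experimental pairs per volunteer,
individual rates frequently hit 0 or 1, where z is infinite. The primary
analysis therefore pools responses over volunteers within a condition and
computes SDT metrics from the pooled rates; uncertainty comes from a
volunteer-level bootstrap rather than per-subject variances. Two escape
hatches exist and are deliberately separate:

- `corrected_rate()` applies the log-linear correction
  (x + 0.5)/(n + 1) for opt-in per-subject SDT
  (`analysis_config(per_subject_sdt = TRUE)`);
- `fit_roc_zspace()` *drops* operating points with a rate of exactly 0 or
  1 rather than correcting them, because the pooled sweep points it is
  designed for are interior; silently correcting a boundary point would
  distort the fitted line.

A fitted slope ≤ 0 is flagged as an improper ROC with a warning rather
than an error: tiny samples can produce one, and the caller should see the
fit to diagnose it.

## Inference choices

**Bootstrap.** Volunteers are the resampling unit — all of a volunteer's
responses move together, respecting the clustered design — with percentile
intervals at 95% and B = 2000 by default (B and the percentile form are
our choices; they give stable intervals at cohort sizes of 100–230).
Replicates where a statistic is undefined (a resample can saturate a rate)
are dropped; if more than half fail the interval is refused rather than
quietly reported. Intervals are bit-reproducible given the seed.

**Per-item tests.** Each face pair's rating distributions under the
"same" vs "different" label come from *independent* volunteer groups
(the version counterbalancing shows each volunteer a given pair under
exactly one label). We therefore use a two-sample rank-sum test as the
primary per-item test, even though such comparisons are sometimes labelled
with the signed-rank name; a genuinely paired signed-rank variant is
available via `paired = TRUE`. The rank-sum test uses average ranks under
ties and exact enumeration of all group assignments when both groups have
≤ 8 observations (ties included, which is why it is implemented here
rather than delegated); larger samples use the tie-corrected normal
approximation without continuity correction. Per-item p-values are
reported unadjusted — matching how such item-level scans are convention-
ally reported — with a Holm-adjusted column emitted alongside for readers
who want it; the headline significance flags use the unadjusted values.

**ANOVA layouts.** Rates per volunteer feed a one-way ANOVA across survey
variants and a repeated-measures ANOVA for the within-subject label effect.
The repeated-measures default pools the two sourced variants (within-effect
error df = n_subjects − 1, e.g. F(1, 222) at 223 subjects); passing
`between =` adds the source as a between-subjects factor, the alternative
layout when the question is whether human and computer sources differ.
Proportions enter untransformed — no arcsine or logit — since the rates sit
well inside (0, 1) at these cohort sizes and the published analyses are on
the raw rate scale.

## The synthetic survey generator

`sim_config()` + `simulate_raters()` + `simulate_survey()` generate
response tables with the statistical structure the analysis assumes, so
every stage (and its parameter-recovery behaviour) is testable without
human-subjects data:

- **Design**: 3 variants × default 120 volunteers, 12 experimental pairs
  (6/6), 2 celebrity catch pairs, two versions counterbalancing labels so
  each pair is seen under both labels across volunteers.
- **Observers**: per-volunteer d′ ~ N(1.4, 0.3²) truncated at 0
  (a screened population should not contain negative sensitivity).
- **Response scale**: six boundaries 0.4 latent units apart, symmetric
  about the population midpoint d′/2. The spacing is our calibration: at
  d′ = 1.4 it puts the headline (θ = 0.5) criterion at 0.20, and the
  resulting pooled rates (TPR ≈ 0.70, FPR ≈ 0.19 in the control arm)
  match the published control-condition operating point, whose implied
  criterion is 0.16.
- **Label effect**: a prior label shifts *all six boundaries* by −δ/2
  ("same") or +δ/2 ("different"), with δ = 0.22 by default — the
  published criterion gap (0.27 − 0.05). Shifting boundaries rather than
  evidence keeps d′ manifestly untouched, which is the hypothesis the
  generator encodes: labels move the criterion, not sensitivity.
- **Catch pairs**: latent means sit ±3 latent units from the boundary
  midpoint, so a compliant observer essentially never fails;
  `catch_fail_rate` plants deliberate failures to exercise screening.

What the generator does **not** model: item-difficulty heterogeneity (the
analysis pools items; per-item tests on synthetic data are null checks,
not effect reproductions), demographic structure (profiles are
exchangeable), trust-response dependence on behaviour, and any
unequal-variance or dual-process evidence distribution. Passing tests on
synthetic data therefore certify the estimators and the pipeline plumbing,
not the psychology of real raters.

## Numerical and edge-case conventions

- Thresholds must be non-integral: ratings are integers, so ties with θ
  are impossible by construction (`binarize_rating` uses strict `>`).
- Screening: the published rule is only "failed to correctly respond" on
  celebrity pairs. Our default counts "not sure" (0) as a failure — the
  catch pairs are meant to be easy, so an unsure answer signals
  non-compliance — and `catch_rule(unsure_fails = FALSE)` relaxes this,
  since the strict reading is a choice, not a reported fact.
- Degenerate statistics are defined rather than left NaN where a defined
  value is the natural limit: one-way F = 0 when there is no variation at
  all; the within-subject F = 0 when the effect sum of squares is at
  numerical zero; the across-item shift test reports an infinite statistic
  with p = 0 (flagged `degenerate`) when all item differences are equal
  and non-zero.
- Duplicate volunteer × item rows are a hard error (the nested design
  makes them ambiguous); missing demographics only drop a volunteer from
  demographic tables, never from the SDT analysis.
- Presentation rounding is round-half-even at 2 decimals, and every
  presentation file has a full-precision sibling; the full-precision file
  is canonical.

## Problem sizes and reproducibility

The bundled analysis scripts simulate 126 volunteers per variant with an
8% planted catch-failure rate (≈ 340 analyzed after screening, close to
the published cohort) and B = 2000 bootstrap replicates. The test suite
runs the same machinery at smaller sizes chosen for precision per unit
time: Monte-Carlo properties are asserted on averages over 25–40 replicate
surveys (a single survey's criterion-gap estimate has sd ≈ 0.05–0.07, so
single-draw assertions would be noise), bootstrap coverage uses 300
replications of a 40-volunteer cohort at B = 400, and the Az-neutrality
simulation in the acceptance tests uses 1000 raters per condition so that
sampling noise (sd ≈ 0.003 in Az) is small against the 0.02 bound being
demonstrated — at the published cohort sizes the max-pairwise-Az statistic
is dominated by binomial noise (median ≈ 0.013, but with a long upper
tail), which the median-based acceptance target accounts for. Every
stochastic step takes an explicit seed; reports, simulated surveys, and
bootstrap intervals are bit-reproducible from (input, config, seed).

## Interface

The package's functions are the interface, and the numbered scripts under
`analysis/` are thin narrative drivers over them (simulate → screen →
analyze → recovery); there is no shell wrapper because the artifact is an
analysis, not a deployment tool. `run_full_analysis()` orchestrates
everything and `render_report()` writes the report sections
(`table4_rates_by_source`, `table5_rates_by_prior`, `table6_sdt`,
`fig4_item_tests`, `fig5_roc_points`/`fig5_roc_fits`, `table2_blocking`,
`trust`, `anova`, `exclusions`) as CSV plus a single JSON document.

```{r example, eval = FALSE}
library(matchbias)

records <- simulate_survey(simulate_raters(sim_config(seed = 42)))
report <- run_full_analysis(records, config = analysis_config(
  bootstrap = bootstrap_config(B = 2000, seed = 5)))
report$sdt          # pooled d' and criterion per prior-label condition
report$roc_fits     # z-space ROC fits and Az per condition
render_report(report, "report_dir")
```

## Known limitations

- The equal-variance assumption is untested against real rating data here;
  unequal-variance (z-slope ≠ 1) ROCs would need a maximum-likelihood
  rating-model fit, which is out of scope.
- Pooled-rate SDT weights volunteers by trial count (equal here) and hides
  between-volunteer criterion variance inside the bootstrap; per-subject
  SDT with the log-linear correction is available but biased at 6 trials
  per rate.
- The z-space OLS ignores point-wise sampling variance (no weighting); with
  six well-populated grid points the effect on Az is small relative to the
  bootstrap uncertainty reported alongside.
- Exact rank-sum enumeration is combinatorial; beyond 8 + 8 observations
  the normal approximation takes over by design.
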