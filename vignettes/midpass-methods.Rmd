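---
title: "Anchor-based MID and PASS estimation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based MID and PASS estimation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midpass)
```

## The problem

Patient-reported outcome measures such as the pain NRS (0–10) and the
PRWHE (0–100, with 0–50 pain and function subscales; lower is better)
are easy to collect and hard to interpret: a 2-point drop on the NRS is
meaningless until it is tied to what patients themselves experience as
change. Two interpretability thresholds do that job:

* the **minimal important difference (MID)** — the smallest *change*
  score patients perceive as an important improvement; and
* the **patient acceptable symptom state (PASS)** — the *state* score at
  or below which patients consider themselves well.

Both are estimated against external *anchors*: a five-level global
rating of change (GRC: much better, somewhat better, unchanged, somewhat
worse, much worse) for the MID, and a yes/no "would you be satisfied if
your condition stayed like this" question for the PASS. `midpass`
implements the full estimation pipeline for longitudinal cohorts in
which each patient contributes one anchor–outcome pair per follow-up,
pooled across follow-ups.

## Data model

A cohort is a long-format table of one record per patient and timepoint
(baseline plus five follow-ups). Change scores are defined as baseline
minus follow-up, so positive change means improvement on these
lower-is-better instruments; consequently credible GRC–change
correlations are *negative* (GRC code 1 is "much better"), and
credibility is judged on the magnitude. Pairs missing the anchor or the
score required by an analysis are excluded for that analysis only, and
every exclusion is counted and reported. No imputation is performed.

## The four MID estimators

Let \(X\) be the change score and let the GRC be dichotomised between
"unchanged" and "somewhat better" (so the improved set is
\{somewhat better, much better\}, the reference set \{unchanged\}, and
deteriorated pairs are excluded — configurable via
`grc_dichotomization()`).

* **Mean change (MC).** \(\widehat{\mathrm{MID}} = \bar X\) over pairs
  rating themselves exactly "somewhat better" — the smallest perceived
  improvement. Simple, but uses half the information and misclassifies
  by construction.
* **Mean difference of change (MDC).**
  \(\bar X_{\text{somewhat better}} - \bar X_{\text{unchanged}}\).
  Robust to shared offsets (it is shift-invariant), but sensitive to a
  noisy "unchanged" mean in small groups.
* **ROC.** The empirical ROC curve of \(X\) discriminating improved
  from unchanged pairs is built over candidate thresholds at the
  midpoints between adjacent distinct observed scores (an integer
  change grid therefore yields half-integer cut points), plus the two
  degenerate endpoints. The MID is the threshold closest to the
  top-left corner, \(\min \sqrt{(1-Se)^2 + (1-Sp)^2}\), with exact ties
  broken toward higher sensitivity and then the smaller absolute
  threshold so the result is deterministic.
* **Predictive modelling.** A logistic regression
  \(\operatorname{logit} P(\text{improved}) = C + B X\) is fitted to
  the improved-vs-unchanged pairs; the MID is the change value at which
  the likelihood ratio for improvement equals one,
  \[
    \widehat{\mathrm{MID}} = \frac{\ln(\text{pre-odds}) - C}{B},
    \qquad \text{pre-odds} = n_{\text{improved}}/n_{\text{reference}},
  \]
  i.e. the point where the posterior odds of improvement equal the
  pre-test odds. The unadjusted variant \(-C/B\) (the 50% posterior
  probability point, equal to the adjusted one under balanced classes)
  is also computed and stored, with the prevalence-adjusted value as
  the default. Fits that separate or give a non-positive slope are
  rejected with a pointer to the ROC method.

AUCs are the Mann–Whitney estimate (ties counted one half), identical
to the trapezoidal area under the constructed curve, with confidence
intervals from DeLong's placement-value variance
(\(\widehat{V} = S_{10}/m + S_{01}/n\), Wald interval truncated to
\([0,1]\); perfect separation yields a degenerate interval plus a
warning rather than an error). AUC above 0.8 is labelled excellent
discrimination, 0.7–0.8 acceptable (the boundary 0.8 counts as
acceptable), below 0.7 poor.

## The two PASS estimators

PASS is a state concept: both methods use follow-up state scores, never
change scores, and lower (better) states are the "positive" class.

* **75th percentile.** The 75th percentile of the state scores of the
  satisfied pairs, with the linear-interpolation quantile definition
  \(h = (n-1)p + 1\) (R's type 7, the common scientific-computing
  default; with ~125 satisfied pairs the choice of quantile rule moves
  the estimate by less than one score unit, and the rule used is
  recorded in the result).
* **ROC.** The optimal cut point (same corner criterion) discriminating
  satisfied from unsatisfied pairs; sensitivity is the proportion of
  satisfied pairs at or below the threshold, specificity the proportion
  of unsatisfied pairs above it.

## Anchor credibility

`validate_anchor()` reports Spearman correlations (mid-rank ties, the
GRC treated as ordinal 1–5) between the GRC and baseline score,
follow-up score and change score, each with a percentile bootstrap CI.
The anchor is flagged credible when \(|\rho_{\text{change}}| > 0.5\);
the baseline and follow-up correlations are reported without a
pass/fail judgement since no accepted threshold exists for them.
Per-timepoint scopes warn below 10 pairs.

## Uncertainty: bootstrap choices

Confidence intervals for the MID estimates re-run the full estimator on
each of (by default) 1000 resamples and take the percentile interval —
the simplest seed-reproducible choice. Two resampling units are
offered:

* **pair** (default): resample anchor–outcome pairs, matching the
  pooled-pairs analysis convention;
* **patient**: a cluster bootstrap resampling whole patients. Pairs
  within a patient are positively correlated (a patient random effect),
  so the pair-level bootstrap is mildly anti-conservative on pooled
  data; in the package's own simulations at 50 patients × 5 follow-ups
  the pair-level 95% interval for the change-score Spearman rho covers
  the population value about 88–89% of the time, the patient-level
  interval about 94–95%. The pair-level default mirrors the pooled
  analysis; the cluster option is the calibrated alternative.

Resamples on which a statistic is undefined (e.g. an empty anchor
group) are redrawn up to a cap, counted, and the interval fails if more
than 20% of replicates stay undefined. Degenerate (point-mass)
intervals are reported with a warning rather than suppressed.

## The synthetic cohort generator

No raw patient-level data ship with the package; `generate_cohort()`
draws cohorts with the statistical structure the estimators assume,
with known ground truth for parameter-recovery testing
(`true_parameters()`). The default configuration emulates a
base-of-thumb osteoarthritis cohort treated with six weeks of splinting
followed by trapeziectomy: 50 patients, baseline and five follow-ups
(250 anchor–outcome pairs), baseline moments NRS 6.5 (SD 1.7), PRWHE
pain 34.2 (6.8), function 30 (7.9); the total is generated as
pain + function (so additivity holds exactly; the implied total mean
64.2 and SD ≈ 12 match that population closely). Baselines are
correlated normals (shared severity factor, correlation 0.35) clipped
to the instrument ranges — with these moments the clipped tail mass is
negligible — with NRS and PRWHE pain rounded to integers and PRWHE
function to half points.

The latent model: each patient carries a recovery random effect
(SD 0.20) around a mean recovery curve (fractions 0.10, 0.25, 0.35,
0.40, 0.45 of the instrument range recovered at the five follow-ups,
plus per-occasion fluctuation SD 0.10). Observed follow-up scores are
the baseline minus the true improvement plus measurement noise (SD 1
NRS point, 3 PRWHE subscale points), clipped and rounded. The GRC is
driven by *true* improvement — perceived change \(10f\) plus anchor
noise (SD 0.8) cut at thresholds (−5.5, −1.5, 2.5, 3.5) on the 0–10
scale — not by the observed change, which creates the realistic
imperfect-anchor setting (AUC < 1) the estimators must handle; setting
the noise SDs to zero recovers the oracle case in which the GRC is a
deterministic step function of improvement. The third threshold is the
generator's true MID: 2.5 in tenths of the instrument range (2.5 NRS
points, 25 PRWHE total points). Satisfaction is a logistic in the
overall symptom state (0.6 × NRS + 0.4 × scaled PRWHE total, reflecting
that satisfaction tracks residual pain most), with 50% satisfaction at
state 2.5 on the 0–10 scale (the true PASS) and scale 0.55.
Missingness, when requested, is completely at random per field.

These defaults were calibrated, once, so that the generated regime
matches the qualitative behaviour reported for such cohorts — pooled
\(|\rho_{\text{change}}|\) between 0.5 and 0.9, excellent
discrimination (AUC > 0.8) for all four instruments, and ROC-based PASS
values at or slightly above the 75th-percentile ones — and so that the
anchor-threshold estimators are consistent for the generator's truth. A
point worth making explicit: the ROC and predictive estimators converge
to the crossing point of the class-conditional change densities, not
automatically to the latent band boundary, so recovery of the "true"
MID requires the latent improvement distribution to be locally balanced
around that boundary. The calibrated defaults satisfy this; a user who
makes the recovery curve pile mass on one side of the threshold will
see the well-known upward (or downward) bias of anchor-based cut
points. That bias is a property of the methods, faithfully reproduced,
not a defect of the implementation.

What the generator does *not* emulate: informative missingness,
learning/response-shift effects in the anchor, instrument-specific
improvement profiles (all instruments share one latent recovery), and
distinct splinting-vs-surgery treatment phases. Passing recovery tests
on these cohorts therefore demonstrates correctness of the estimators
under the stated model, not validity of any particular clinical
threshold.

## Numerical conventions and degenerate inputs

* Candidate ROC thresholds never coincide with observed scores, so
  classification at a threshold is unambiguous; strict and non-strict
  comparison coincide.
* Cut-point distance ties are resolved at tolerance 1e−12 toward higher
  sensitivity, then smaller |threshold|.
* Single-class anchors, empty anchor groups, and logistic separation
  are errors with actionable messages; n = 1 groups and zero-variance
  AUCs produce degenerate intervals with warnings.
* All stochastic operations take an explicit seed and leave the
  caller's RNG state untouched; identical configuration (including
  seed) reproduces byte-identical cohorts and artifacts.
* Simulation-based checks in the test suite use deliberately scaled
  problem sizes — 100 patients (500 pairs) for parameter recovery over
  50 seeds, 200 replicates at 50 patients for bootstrap coverage, 20
  binormal replicates at 200 per class for the DeLong/bootstrap
  comparison — the sizes at which these properties are informative for
  the study design the package targets.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(synthetic_config(seed = 1))
pairs <- build_pairs(coh, "nrs", require_anchor = "either")

validate_anchor(pairs[!is.na(pairs$grc), ], n_boot = 1000, seed = 1)
summary(mid(pairs, "roc", n_boot = 1000, seed = 1))
summary(pass(pairs, "roc", n_boot = 0))

# all instruments, all methods, plus artifacts on disk:
res <- run_pipeline("all", out_dir = "midpass_run", n_boot = 1000, seed = 1)
res$mid
res$pass
```

## Known limitations

* Only the four registered instruments are handled; adding an
  instrument means extending the registry (documented extension point,
  deliberately not exposed as API).
* No distribution-based MID methods (SEM, 0.5·SD) and no
  deterioration-direction thresholds.
* No smoothed/binormal ROC fitting, partial AUC, or paired comparison
  of two correlated AUCs.
* MID/PASS cut points are group-level interpretive aids; they are not
  valid decision rules for individual patients, and the package makes
  no attempt to model the time-dependence of the thresholds (pooling
  across follow-ups is the default precisely because per-timepoint
  subsets are small).
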