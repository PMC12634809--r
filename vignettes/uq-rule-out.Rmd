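---
title: "Uncertainty-based rule-out for semi-autonomous csPCa detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-based rule-out for semi-autonomous csPCa detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqtriage)
```

## The problem

Prostate MRI reading for clinically significant prostate cancer (csPCa,
Gleason Grade Group ≥ 2) is radiologist-limited: every visit must be read,
and reading volumes keep growing. A deep-ensemble detection model offers a
way out if its *uncertainty* can be trusted: visits on which the ensemble is
confidently right can be reported autonomously ("ruled out" of the
radiologist's worklist), and only the ambiguous remainder referred for human
reading. `uqtriage` implements the evaluation machinery for such a
semi-autonomous pathway: the uncertainty metrics, the triage rules, the
combined-pathway accuracy accounting, and the inference needed to claim a
workload reduction at non-inferior accuracy.

## Uncertainty metrics

Each visit carries $K$ submodel likelihoods $s_1,\dots,s_K \in [0,1]$
(default $K = 15$). The patient-level AI prediction is the ensemble mean
$\bar p = \frac1K \sum_k s_k$. Two certainty scores are derived from it:

* **meanUQ** $= |\bar p - 0.5|$. Mean predictions near 0 or 1 are confident
  calls in either direction; predictions near 0.5 are ambiguous. Higher
  meanUQ = more certain. Range $[0, 0.5]$.
* **varUQ** $=$ the standard deviation of $s_1,\dots,s_K$. Disagreeing
  submodels signal an unreliable prediction. Lower varUQ = more certain.
  Range $[0, 0.5]$ for scores in $[0,1]$.

The standard-deviation divisor is the population divisor $K$ (the submodels
*are* the whole ensemble, not a sample of a larger one); the $K-1$ divisor is
available through `var_uq(..., divisor = "sample")` since published variants
do not state their choice. Both metrics are compared to thresholds through a
single orientation-aware comparator (`is_certain()`), so the opposite
orientations cannot be confused anywhere downstream.

## The rule-out pathway

Given a certainty flag per visit (by metric threshold, `triage_by_threshold()`,
or by a requested autonomous fraction, `triage_by_fraction()`):

* certain visits get the autonomous AI diagnosis $\mathbb 1\{\bar p \ge \tau_{AI}\}$;
* uncertain visits get the radiologist's clinical-practice call
  (PI-RADS ≥ 4).

`pathway_metrics()` scores the combined diagnoses against biopsy ground
truth over *all* visits regardless of reader, and reports the radiologist
workload as the uncertain fraction. Rates with an empty denominator
(a stratum with no positives or no negatives) are reported as `NA`, never
coerced to zero, and excluded from resampling statistics.

`triage_by_fraction(f)` flags exactly $\lfloor f \cdot n \rfloor$ visits
(the autonomous share never exceeds the request), ranked most-certain first
with `visit_id` as the final tie-break key — deterministic across platforms.

## Operating-point calibration

A fair sensitivity comparison requires matching specificity. The pathway's
specificity is a non-decreasing step function of $\tau_{AI}$, so
`calibrate_ai_threshold()` scans all achievable operating points (midpoints
between sorted unique certain-case mean predictions, with 0 and $+\infty$ as
sentinels — mean predictions are bounded below by 0) and returns the smallest
threshold whose combined specificity reaches the target; that choice
maximizes sensitivity subject to the constraint. The target is the
radiologist's specificity minus a non-inferiority margin (0.05 or 0.10 by
default): the margins trade extra biopsies for workload reduction. If even
an all-negative AI cannot reach the target the result is flagged
unattainable, with the maximum achievable specificity attached.

## Threshold selection by Youden's index

For experiment 1 the rule-out threshold itself is selected with Youden's
index ($J = \text{sensitivity} + \text{specificity} - 1$). An uncertainty
threshold is not itself a csPCa classifier, so which classifier's $J$ is
maximized over the uncertainty threshold is a genuine design choice;
`youden_uq_threshold()` isolates it behind a strategy switch:

* `"subset_youden"` (default): for each candidate uncertainty threshold, the
  mean prediction is evaluated on the resulting certain subset at the
  subset's own Youden-optimal cut, and the candidate with the best subset $J$
  wins; ties go to the larger certain subset. This directly optimizes "the
  detection achievable on what is ruled out", but on cleanly separable data
  it favors small, perfectly classified subsets ($J = 1$).
* `"error_youden"`: the certainty score is treated as a predictor of whether
  the AI's own diagnosis (mean prediction at its full-cohort Youden cut) is
  correct, and the threshold is the Youden-optimal cut of that correctness
  ROC. On the synthetic cohort this yields certain fractions in the 25–55%
  range, closer to what is typically reported for ensembles of this kind.

Plain `youden_threshold()` uses candidate cut points at midpoints of sorted
unique scores with $\pm\infty$ sentinels — every achievable confusion table
is visited exactly once — and breaks ties in $J$ toward higher specificity.

## Inference

* **DeLong test** (`delong_test()`): the structural-components estimator of
  AUROC variance and covariance, computed via midranks; two-sided normal test
  on the AUROC difference. Paired mode estimates the covariance from the
  shared cases; unpaired mode (used when comparing the two metrics' different
  certain subsets) sets it to zero. `pROC`'s implementation serves as an
  independent cross-check in the test suite, not as the implementation.
* **Permutation test** (`permutation_sensitivity_test()`): observed statistic
  is the pathway-minus-radiologist sensitivity difference; the null swaps the
  two diagnosis sources with probability 1/2 *per patient* (all of a
  patient's visits together), honoring repeat visits. The p-value uses the
  add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$ with
  $B = 10\,000$ by default. The default alternative is one-sided (greater) —
  the question asked is *superior* sensitivity at a non-inferior specificity —
  with `"two.sided"` available by flag.

No multiple-testing correction is applied across centers, mirroring the
evaluation design this package implements; interpret per-center p-values
accordingly.

## The synthetic cohort generator

No clinical cohort ships with the package; `generate_cohort()` draws one
with the statistical structure the analysis assumes. Defaults
(`default_cohort_spec()`) follow the multicenter csPCa cohort structure the
pipeline is designed around:

| center | visits | prevalence | radiologist sens/spec |
|--------|-------:|-----------:|----------------------:|
| A      | 689    | 25%        | 83% / 58%             |
| B      | 723    | 25%        | 86% / 54%             |
| C      | 200    | 27.5%      | 95% / 78%             |

Per visit the generator draws truth ~ Bernoulli(prevalence); a latent logit
signal $z = \pm\,\texttt{ai\_separation}/2 + \mathcal N(0, \texttt{latent\_sd}^2)$;
and $K$ submodel scores $\mathrm{logit}^{-1}(z + e_k)$ with
$e_k \sim \mathcal N(0, \sigma^2)$, where $\sigma$ is
`ensemble_sd_certain` or `ensemble_sd_uncertain` according to a per-case
Bernoulli(`uncertain_mix`) regime draw. The logit-normal mixture guarantees
scores in $[0,1]$ and separates the two knobs: `ai_separation` controls the
AUROC of $\bar p$ (and meanUQ), the dispersion mixture controls varUQ.
Defaults: `ai_separation = 1.5` and `latent_sd = 1` (full-cohort AUROC
$\approx \Phi(1.5/\sqrt 2) \approx 0.85$, a realistic operating range for
current csPCa detection models); `ensemble_sd_certain = 0.15`,
`ensemble_sd_uncertain = 1`, `uncertain_mix = 0.35`, giving roughly
two-thirds concordant and one-third discordant ensembles;
`pirads3_rate_neg = 0.3` of radiologist-negative benign cases scored
PI-RADS 3 (biopsy-triggering but below the positive call).

PI-RADS assignment: a csPCa case is PI-RADS 4 or 5 (uniform split) with
probability `rad_sensitivity`, and PI-RADS 3 otherwise — PI-RADS 1–2 cases
are never biopsied under clinical rules, so they cannot carry a positive
ground truth; assigning 3 directly is the fixed point of redrawing an
invalid negative-branch draw and, unlike a rejection loop, leaves the
empirical sensitivity at its configured value. A benign case is PI-RADS 4–5
with probability 1 − `rad_specificity`, else PI-RADS 3 with probability
`pirads3_rate_neg`, else 1–2 (uniform).

Seeding: one integer seed; each center draws from a substream at a fixed
offset, so a center's records are reproducible regardless of which other
centers are in the spec. `repeat_visit_rate` (default 0) lets a fraction of
visits reuse earlier patient ids, exercising the patient-level permutation
unit.

**What the generator does not emulate.** Real ensembles' disagreement
distribution is unknown; the two-regime logit-normal mixture is a stand-in
chosen for controllability, not realism. There is no image-quality,
scanner, PSA or age structure, no correlation between radiologist errors and
AI errors (in practice both read the same images, so their errors correlate),
and no per-lesion structure. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated, not that any particular clinical
workload reduction is achievable; clinical AUROCs and workload percentages
depend on the real cohort and detection model and are out of scope.

## Numerical choices and degenerate inputs

* Certainty at a threshold is inclusive (`>=`/`<=` on the certain side).
* Candidate-threshold grids use midpoints of sorted unique values; the lower
  sentinel for mean-prediction thresholds is 0 (scores are bounded), and
  $\pm\infty$ elsewhere.
* Percentages in result tables are rounded half-even to 2 decimals — one
  fixed convention so table equality tests are well-defined.
* Single-observation structural components contribute zero (not missing)
  variance; a zero-variance AUROC difference of exactly zero yields
  $z = 0, p = 1$.
* Empty certain sets, single-class subsets and unattainable specificity
  targets are surfaced explicitly (`NA` rates, `attainable = FALSE`, or an
  error naming the condition) rather than silently coerced.

## Problem sizes in the test suite

The suite verifies the AUROC, Youden and calibration code against exhaustive
oracles at n ≤ 200, DeLong variances against directly coded structural
components at n = 20, permutation-test type-I error over 500 exchangeable
null cohorts of 150 patients at 999 permutations, DeLong null rejection over
1000 replicate pairs of 120-case samples, and generator parameter recovery at
n = 5000 against 99% binomial bands. These sizes give each check enough
resolution to fail meaningfully while keeping the default run fast; the
calibration replicate size matters because a heavily discrete permutation
statistic is conservative by construction and would measure discreteness
rather than calibration.

## A worked run

```{r example, eval = FALSE}
cohort <- add_ensemble_summary(generate_cohort(default_cohort_spec(seed = 1)))

# Experiment 1: compare the two metrics' rule-out
run_experiment1(cohort)

# Experiment 2: workload sweep at non-inferior specificity
e2 <- run_experiment2(cohort, metric = "varUQ", n_perm = 10000, seed = 1)
render_reports(e2, "results")
```

## Known limitations

The two Youden concretizations above are both defensible, and they can
select very different
certain fractions; conclusions about *which metric rules out more cases*
depend on that choice. The permutation test assumes exchangeability of the
two diagnosis sources within patient under the null; it does not model
reading-time differences, and the pathway evaluation inherits any bias in
using clinical reads both as comparator and (for PI-RADS 1–2) as ground
truth.
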