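# uqtriage

Evaluation machinery for **semi-autonomous AI diagnosis with
uncertainty-based rule-out**, built around clinically significant prostate
cancer (csPCa, Gleason Grade Group ≥ 2) detection on prostate MRI. A deep
ensemble of detection submodels produces, per visit, likelihoods
$s_1,\dots,s_K \in [0,1]$; visits on which the ensemble is *certain* are
reported autonomously by the AI, and the rest are referred to a radiologist.
The package quantifies how much radiologist workload such a pathway can
remove while keeping sensitivity at a **non-inferior specificity operating
point**, and provides the inference to back the claim.

It is aimed at researchers evaluating reject-option / selective-prediction
designs for diagnostic AI: it ships the metrics, the triage and calibration
rules, the statistics, and a synthetic multicenter cohort generator so the
whole pipeline runs and is testable without any clinical data.

## The model in brief

With $\bar p = \frac1K\sum_k s_k$ the ensemble mean prediction:

* **meanUQ** $= |\bar p - 0.5|$ — higher is more certain;
* **varUQ** $= \mathrm{sd}(s_1,\dots,s_K)$ (population divisor) — lower is
  more certain.

Certain visits get the autonomous call $\mathbb 1\{\bar p \ge \tau_{AI}\}$,
uncertain visits the radiologist's PI-RADS ≥ 4 call. $\tau_{AI}$ is
calibrated so the combined pathway's specificity is at least the
radiologist's specificity minus a margin (0.05 / 0.10), and the pathway's
sensitivity is compared to the radiologist's with a patient-level
permutation test (10 000 permutations; patients, not visits, are the
resampling unit). Rule-out thresholds are selected by Youden's index;
meanUQ- and varUQ-selected certain subsets are compared by AUROC with the
DeLong test (structural components, unpaired across differing subsets).

## Worked example

```r
library(uqtriage)

cohort <- add_ensemble_summary(generate_cohort(default_cohort_spec(seed = 1)))
cc <- cohort[cohort$center_id == "A", ]

radiologist_metrics(cc)
#>    tp  fp  tn fn sensitivity specificity n_certain n_total workload_radiologist
#> 1 130 220 302 37   0.7784431   0.5785441         0     689                    1

e2 <- run_experiment2(cc, metric = "varUQ", margins = 0.10,
                      fractions = c(0, 0.2, 0.5), n_perm = 10000, seed = 1)
e2[, c("fraction_ai", "achieved_specificity", "pathway_sensitivity",
       "radiologist_sensitivity", "p_value", "workload_radiologist")]
#>   fraction_ai achieved_specificity pathway_sensitivity radiologist_sensitivity
#> 1         0.0                0.579               0.778                   0.778
#> 2         0.2                0.479               0.820                   0.778
#> 3         0.5                0.479               0.844                   0.778
#>   p_value workload_radiologist
#> 1  1.0000                1.000
#> 2  0.0079                0.801
#> 3  0.0025                0.501
```

Reading the rows: at 0% autonomous reading the pathway *is* the radiologist
(sensitivity 0.778 at specificity 0.579, p = 1 by construction). Ruling out
the 20% most-certain visits by varUQ, with the AI threshold calibrated to
the non-inferior specificity target 0.579 − 0.10, raises sensitivity to
0.820 (one-sided permutation p = 0.0079) while the radiologist reads only
80.1% of visits. `run_experiment1()` produces the per-center metric
comparison (thresholds, certain-case percentages, certain-subset AUROCs,
DeLong p, overlap shares), and `render_reports()` writes the tables and
sensitivity-versus-fraction figures.

A thin CLI over the same functions is included:

```sh
Rscript inst/scripts/uqtriage.R simulate --seed 1 --out cohort.csv
Rscript inst/scripts/uqtriage.R all --cohort cohort.csv --n-perm 10000 --out results/
```

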