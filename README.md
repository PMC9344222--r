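# aaostab

Bootstrap stability selection for age-at-onset prediction models.

## What this package is for

The age at onset (AAO) of bipolar disorder stratifies patients into
clinically distinct subgroups, and the psychosocial factors associated with
it — childhood abuse, premorbid substance use, temperament, life events —
are natural candidates for early-intervention triage. Identifying which of
~28 such mixed-type predictors carry signal in a cohort of ~1000
participants is a sparse variable-selection problem on a positive outcome.
`aaostab` implements that analysis end to end for biostatisticians working
with cohort tables: preprocessing, a from-scratch penalized solver,
bootstrap stability selection, modal-coefficient reporting, and held-out
calibration — plus a synthetic cohort generator so the whole pipeline is
testable without access to any restricted data.

## The method

AAO is modelled on the natural-log scale,
`log(AAO_i) = b0 + x_i'b + e_i`, with the elastic-net objective

    (1/2n) * sum_i (y_i - b0 - x_i'b)^2  +  lambda * [ a*||b||_1 + (1-a)/2*||b||_2^2 ]

minimized by cyclic coordinate descent (`a = 1`, the LASSO, by default).
Because L1 fits carry no standard errors, inference is by stability
selection: B bootstrap resamples of the training set, 10-fold
cross-validation on each resample to find the MSE-minimizing `lambda`,
coefficients recorded at that `lambda`, and predictors retained when their
coefficient is nonzero in **strictly more than 90%** of resamples. Each
retained predictor is summarized by its *modal coefficient* (midpoint of the
fullest 0.001-wide histogram bin of its draws). The selected set is refit by
ordinary least squares and scored on a held-out 30% split with R², the
exponentiated mean absolute error (a multiplicative error in years), and a
LOESS calibration curve (span 0.3) against the 45° line.

## Worked example

```r
library(aaostab)
cfg <- run_config(
  cohort = default_cohort_spec(n = 1022),  # synthetic cohort, 28 predictors,
                                           # 11 true effects on log-AAO
  master_seed = 1,
  stability = stability_config(B = 200),
  penalty = penalty_config(alpha = 1, K = 10),
  comparison_alphas = 0.5
)
res <- run_pipeline(cfg)
print(res)
```

```
pipeline_result: 1022 analysed rows; 17 selected predictors
stability_result: 200 resamples x 30 encoded columns
  selected (freq > 0.9 ): 17 predictors
                                  column inclusion_freq modal_coef
3                        childhood_abuse          1.000    -0.3095
5                 cannabis_use_pre_onset          1.000    -0.2895
14     le_death_close_friend_or_relative          1.000    -0.1725
2                 family_history_suicide          1.000    -0.1425
8                             schizotypy          1.000    -0.0985
10                 irritable_temperament          1.000    -0.0675
7         poor_premorbid_work_adjustment          0.975    -0.0475
9                cyclothymic_temperament          0.965    -0.0275
1               family_history_affective          0.905     0.0005
6              education_level.secondary          0.940     0.0005
11               hyperthymic_temperament          0.930     0.0005
12                 le_marital_separation          0.995     0.0965
4                 alcohol_units_per_week          1.000     0.1455
15                     le_birth_of_child          1.000     0.1915
13 le_death_parent_partner_child_sibling          1.000     0.3195
16        le_seeking_work_unsuccessfully          1.000     0.3705
17             le_major_financial_crisis          1.000     0.4175
  lambda: mean = 0.001273  s.d. = 0.0006974 
calibration_report: n_test = 307 
  R^2 = 0.491 | MAE(log) = 0.2710 | exp(MAE) = 1.311 | span = 0.30
```

Reading this: the generator planted 11 nonzero effects, and all 11 are
retained with the correct signs and magnitudes close to the planted values
(childhood abuse −0.3095 vs. the true −0.2855; major financial crisis
+0.4175 vs. +0.4575). Negative modal coefficients mean an earlier onset,
positive a later one, per unit of the encoded predictor on the log-age
scale. Six additional predictors clear the 90% rule at this high
signal-to-noise — at the MSE-minimizing `lambda` (mean 0.0013 here) the
LASSO over-selects, and correlated null temperament traits ride along with
small modal coefficients (±0.0005–0.05); the inclusion-frequency table is
reported precisely so such marginal entries can be read for what they are.
Held-out calibration: R² = 0.49 and exp(MAE) = 1.31, i.e. predictions are
off by a factor of ~1.3 in years on average. An elastic-net rerun
(`comparison_alphas = 0.5`) reports whether the mixing choice changes the
selected set (Jaccard 0.895 here).

`run_pipeline(cfg, out_dir = "run1")` additionally writes the coefficient
draws, selection summary, density-curve data, calibration curve, manifest
and a human-readable summary as plain-text files; `inst/scripts/run-pipeline.R`
wraps this for shell use with a YAML config (`?read_run_config`).

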