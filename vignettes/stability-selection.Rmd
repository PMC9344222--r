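---
title: "Bootstrap stability selection for age-at-onset models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap stability selection for age-at-onset models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Age at onset (AAO) of bipolar disorder is a positive, right-skewed outcome
measured in years. `aaostab` models it on the natural-log scale as a sparse
linear function of mixed-type psychosocial predictors:

$$\log(\text{AAO}_i) = \beta_0 + x_i^{\top}\beta + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

where $x_i$ is the encoded predictor vector (0/1 for binary predictors and
dummy levels, z-scores for numeric scores). With ~28 candidate predictors and
roughly a thousand participants, the package selects variables with the
LASSO: the elastic-net objective

$$\frac{1}{2n}\sum_i\bigl(y_i-\beta_0-x_i^{\top}\beta\bigr)^2 +
  \lambda\Bigl[\alpha\|\beta\|_1+\tfrac{1-\alpha}{2}\|\beta\|_2^2\Bigr]$$

is minimized by cyclic coordinate descent with soft-threshold updates
(`fit_enet()`, compiled Gram-form inner loop). $\alpha = 1$ is the LASSO and
the default; $\alpha = 0.5$ is used for the elastic-net sensitivity rerun.
The $\tfrac{1}{2n}$ loss scaling keeps $\lambda$ values on the scale familiar
from the mainstream solvers for this family, so reported penalty magnitudes
are directly comparable.

Because L1 solutions carry no standard errors, inference is by **bootstrap
stability selection** (`run_stability()`):

1. resample the model-development rows with replacement;
2. run 10-fold cross-validation on the resample to find the
   MSE-minimizing $\lambda$ (`cv_select()`; the $\lambda$ grid is recomputed
   on each resample, since the procedure operates on the resample as its
   data);
3. record the resample's coefficients at that $\lambda$;
4. repeat B times (B = 1000 by default; desk-scale analyses in this package
   use B = 200).

A predictor is *selected* when its coefficient is nonzero — exactly nonzero;
the L1 solver produces true zeros — in **strictly more than 90%** of
resamples. For each selected predictor the *modal coefficient* is reported:
the midpoint of the fullest histogram bin of its B draws, with bin width
0.001 anchored at zero. The bin-midpoint convention is why modal values
terminate in a trailing 5 at the fourth decimal; it is configurable
(`mode_bin_width`).

The selected model is then refit **unpenalized** on the training rows
(`refit_selected()`) and scored on the held-out 30% (`calibrate()`): held-out
$R^2 = 1-\mathrm{SS}_{res}/\mathrm{SS}_{tot}$ (which may be negative out of
sample), log-scale MAE, exponentiated MAE (a multiplicative error factor in
years), and a LOESS calibration curve of observed against predicted log-AAO,
where perfect calibration is the 45° line. Modal coefficients are a
descriptive summary of the resampling distribution; since it is not
documented practice which coefficient vector should generate predictions, the
package defaults to the unpenalized refit and offers `modal_model()` as the
sensitivity alternative.

## Preprocessing conventions

`encode()` reproduces the conventional preparation of such cohort tables:

- listwise deletion of any row with a missing outcome or predictor
  (`listwise_delete()`); no imputation;
- removal of rows collected before a 2008 era cutoff (`filter_era()`),
  reflecting instruments that were only administered from that year;
- natural-log transform of AAO (`log_transform_outcome()`), rejecting
  non-positive ages by row;
- K−1 dummy coding of categoricals against the first schema level;
- z-standardisation of numeric predictors with denominator $n-1$. Binary 0/1
  columns are left unscaled: dummy coding and numeric scaling are treated as
  separate conventions, and penalties apply equally to all encoded columns.

Scaling is applied to the **full sample before splitting** by default,
replicating the original convention; `scaling = "train-only"` gives the
leakage-safe alternative (train-set means/s.d.s applied to the test rows).
The phrase "scaling numeric dependent variables" in the source methods is
read as a slip for *independent* variables — the outcome is handled by the
log transform.

`split_cohort()` draws the 70:30 partition with `round(0.7·n)` training rows
under R's round-half-even rule: at n = 1022 this gives 715/307, not the
historically reported 717/305; the discrepancy is a rounding-convention
difference and is left as such rather than reverse-engineered.

## The synthetic cohort generator

No participant-level data from the original cohort are distributable, so
`generate_cohort()` supplies the study conditions: `default_cohort_spec()`
declares 28 predictors — family-history indicators, childhood abuse, weekly
alcohol units, cannabis/other drug use, a 4-level education categorical,
premorbid work/social adjustment, seven personality/temperament scores, and
eleven yes/no life events. Eleven predictors carry the published signed
effects on log-AAO as ground truth (childhood abuse −0.2855 through major
financial crisis +0.4575); the other seventeen are null.

Correlated mixed-type columns come from a **Gaussian copula**: latent
standard normals with a declared correlation matrix are transformed
marginally (binary by prevalence threshold, categorical by level-weight
quantile cuts — equiprobable by default, since level frequencies are not
reported for the categoricals —, numeric kept Gaussian). Only pairwise
correlations are reported for the real data, so a copula is the natural
minimal joint model; the user contract is a symmetric, unit-diagonal, PSD
matrix, and violations are rejected naming the smallest eigenvalue. The
default latent structure places the seven trait scores in a correlated block
spanning r = −0.21 to 0.68, the reported extreme pairwise correlations, with
the strongest correlations among *null* traits so that trait clustering
stresses the selector realistically.

Fixed generator constants, chosen once as field-realistic values:
`intercept_log_age = 3.1` and `noise_sd_log = 0.35`, which give mean
simulated AAO ≈ 23 years with dispersion slightly above the reported
s.d. of 9.86; binary prevalences between 0.08 (rarer life events) and 0.45
(family history of affective disorder), typical of published cohort
frequency tables. Missingness is injected MCAR (`inject_missingness()`),
consistent with the reported equivalence of complete-case and full samples;
the AAO < 65 inclusion criterion is available as an off-by-default
truncation flag because truncation distorts the log-linear generative model.

What the generator does **not** emulate: non-linear predictor–outcome
relationships (e.g. the plausibly non-monotone alcohol effect), informative
missingness, recall bias in self-reported AAO, age-dependent life-event
prevalence, and item-level questionnaire structure. Passing tests therefore
demonstrate that the machinery recovers a known sparse log-linear signal
under realistic correlation and noise — not that the published predictor set
is correct for real cohorts.

## Numerical choices

- Convergence: maximum absolute coefficient change per sweep ≤ `tol`
  (default 1e-7); sweep cap 1e5; every converged fit passes a KKT subgradient
  certificate at 1e-6 in the test suite.
- Path: geometric grid of 100 $\lambda$ values from $\lambda_{\max}$
  (the exact all-zero threshold $\max_j |\langle x_j, y-\bar y\rangle|/(n\alpha)$)
  down to $10^{-4}\lambda_{\max}$ (1e-2 when p ≥ n), warm-started; for
  $\alpha = 0$ the grid is anchored at the $\alpha = 0.001$ threshold.
- CV ties at equal MSE break toward the larger (sparser) $\lambda$; fold
  assignment is uniform and seeded.
- Per-resample seeds derive deterministically from the master seed, so B
  resamples are independent yet the whole run is bit-reproducible; degenerate
  resamples are redrawn with spare derived seeds and the run aborts if more
  than 1% degenerate.
- A zero-variance column (possible inside a bootstrap resample of a rare
  dummy) keeps its coefficient at exactly zero rather than invalidating the
  resample.
- Modal-coefficient bins are half-open $[k w, (k+1) w)$ with a 1e-9 guard on
  the floor so draws on representable bin edges land deterministically; ties
  between equally full bins break toward the bin nearest the median of the
  draws, then toward zero.
- LOESS (`loess_curve()`) is local-linear with tricube weights over the
  span-fraction neighbourhood, computed exactly (direct surface) via
  `stats::loess`; span defaults to 0.3. Pointwise ~95% intervals are
  t-intervals from the local fit's standard errors — the original band
  construction is unspecified, and this is the standard choice. The curve is
  evaluated at the sorted unique predictions, thinned to at most 200 points.

## Problem sizes

The test suite and the acceptance script run the full procedure at
desk scale: cohorts of n = 600–1022, B = 200 resamples, 10-fold CV, 100-point
$\lambda$ grids — sizes at which the favourable signal-to-noise recovery
properties hold and a complete run takes minutes on one core. B = 1000
remains the documented production profile for real analyses.

## A complete run

```{r, eval = FALSE}
library(aaostab)
cfg <- run_config(
  cohort = default_cohort_spec(n = 1022),
  master_seed = 1,
  stability = stability_config(B = 200),
  penalty = penalty_config(alpha = 1, K = 10),
  comparison_alphas = 0.5
)
res <- run_pipeline(cfg, out_dir = "aaostab-run")
print(res)
```

The output bundle contains the coefficient draws, the selection summary with
inclusion frequencies and modal coefficients, kernel-density curves for the
selected predictors, the calibration metrics and curve, an agreement report
for the elastic-net rerun (same-set flag and Jaccard index), and a manifest
echoing every tunable and derived seed.

## Limitations

The procedure inherits the known behaviour of CV-minimizing LASSO: the
MSE-minimizing $\lambda$ over-selects, so stability selection's strict
inclusion rule — not the per-resample fits — carries the error control, and
that control is approximate, not a formal bound (complementary-pairs
variants, which have such bounds, are out of scope). Concretely, on the
package's own favourable-signal test cohorts (n = 600, 11 true effects,
log-noise 0.35), the eleven true-effect predictors are recovered in every
tested seed, but the per-resample $\lambda_{\min}$ is small (~0.002) and
null temperament traits latently correlated (r ≈ 0.35–0.55) with true-effect
traits can exceed the 90% rule, as can — in a minority of seeds — one
spurious predictor under a permuted-outcome control, because a fixed
permutation retains sampling correlations of order $n^{-1/2}$ that every
bootstrap resample then reproduces. The same $\lambda_{\min}$ values and
nonzero counts arise from the mainstream reference solver on identical
resamples, so this is a property of the procedure at high signal-to-noise,
not of the implementation; at the noise level of real cohorts (much larger
penalties, here ~0.018 on comparable scales) the rule is far more
conservative. Users should read the selected set together with the
inclusion-frequency table rather than as an error-controlled discovery
list. Modal coefficients are shrinkage-attenuated relative to unpenalized
refits; the package reports both. Non-Gaussian outcome families and the
1-SE lambda rule are not implemented.
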