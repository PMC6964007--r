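---
title: "Validating JIA risk calculators: models, imputation, and honest resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating JIA risk calculators: models, imputation, and honest resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jiarisk)
```

## The models

Juvenile idiopathic arthritis (JIA) risk calculators are multivariable
logistic regressions over routine baseline variables.  Each model is a
linear predictor

$$A = \alpha + \sum_j \beta_j x_j,$$

mapped to a chance of the outcome $100\,e^A/(1+e^A)$ percent.
`builtin_models()` ships seven coefficient sets: the Canadian
severe-disease-course model (16 predictors, including three JIA-category
indicators with the remaining categories as reference), the Nordic
models for non-achievement of remission and for functional disability
(CHAQ > 0), and four fine-tuned variants of the Nordic non-remission
model re-estimated on the Canadian cohort (for non-remission and for
severe disease course, each with and without the laboratory variables
ESR, CRP > 10 mg/L, ANA, and HLA-B27).  The published and fine-tuned
sets are shipped verbatim as reference constants; their `provenance`
field distinguishes them from models fitted by this package.

One modelling subtlety: the Nordic models were developed on the
*cumulative* joint count within 6 months of onset, but validation
cohorts often only have the baseline active joint count.  The package
therefore scores a single numeric predictor,
`joint_count_for_nordic`, and `load_cohort()` maps whichever column the
user supplies onto it (cumulative if present, otherwise baseline),
announcing the mapping.  Both Nordic VAS terms (physician global
assessment in the remission and disability models) are interpreted as
the 0–10 visual-analogue scale.

Predicted chances are reported on the 0–100 percent scale, as the
calculators print them; every internal computation uses the 0–1 scale,
and each interface documents which one it takes.  Risk strata use the
published cut-points: below 20 % low, above 60 % high, the cut values
themselves intermediate.

## Discrimination and calibration

Discrimination is the tie-aware concordance index: over all
case–control pairs, concordant pairs count 1 and tied-score pairs 1/2,
so `c_index()` equals the trapezoidal area under the ROC polyline that
`roc_points()` emits (one point per distinct threshold).  Ties at 1/2
is the standard AUC convention; the implementation uses midranks
(the Wilcoxon identity), and the test suite checks exact equality with
an $O(n^2)$ pair-counting oracle.

`c_index_se()` is the DeLong structural-components variance — for each
case the fraction of controls it beats, for each control the fraction
of cases it loses to, with the variance of those placement values
divided by the respective class sizes.  This choice is assumption-light
and standard; it is cross-checked against an independent implementation
(pROC) in the tests.  All 95 % intervals in the package are
estimate ± 1.96·SE.

`calibration_deciles()` sorts patients by predicted probability
(stable sort) into 10 near-equal bins, lowest predictions first; when
$n$ is not a multiple of 10 the remainder is distributed one patient
per bin starting from the lowest bin.  Each bin reports its mean
prediction, observed event rate, and count.

## Multiple imputation

`mice_impute()` implements chained equations directly: each incomplete
predictor is regressed on all other predictors and its missing cells
are drawn from the fitted predictive distribution, sweeping columns in
order of ascending missingness.  Methods per type:

* continuous (ESR, VAS scales): Bayesian linear regression —
  residual variance drawn from its scaled inverse-chi-square, slopes
  from their normal posterior, then predictive noise added — i.e.
  approximate proper imputation;
* joint counts: the same draw, rounded and floored at 0;
* binaries: logistic fit, coefficients perturbed by a normal draw from
  their asymptotic covariance, then Bernoulli draws;
* JIA category: multinomial regression (via `nnet`), categories drawn
  from the predicted class probabilities.

Defaults: `M = 20` datasets and `n_iter = 10` sweeps.  Ten sweeps is a
conventional burn-in for chained equations at these missingness levels;
`M = 20` matches the standard practice for cohorts with ~10 % missing
data.  Outcome columns are never imputed, and by default they are also
excluded from the imputation models (`impute_with_outcome = FALSE`), a
deliberately conservative default.  Note that outcome-free covariate
imputation is *uncongenial* with fitting an outcome model on the
completed data: associations passing through imputed cells are
attenuated toward null (in our generator-truth experiments, roughly
10–15 % at 10 % missingness).  When the goal is unbiased coefficient
re-estimation — as in fine-tuning, or in the parameter-recovery checks
of the test suite — set `impute_with_outcome = TRUE`, which is the
standard multiple-imputation recommendation for covariates of a
prediction model.

Each of the M streams is seeded `seed + m`, so a run is bit-reproducible
and changing M leaves the earlier datasets' streams untouched.

## Un-tuned evaluation and fine-tuning

`evaluate_untuned()` scores every patient of every imputed dataset with
the published coefficients — no refitting — computes the C-index and
DeLong SE per dataset, and pools with Rubin's rules: estimate = mean,
total variance $T = \bar W + (1 + 1/M)B$ with $\bar W$ the mean
within-dataset variance and $B$ the between-dataset variance of the
estimates.  `rubin_pool()` exposes the rule directly and guarantees
$T \ge \bar W$.

Fine-tuning re-estimates the intercept and coefficients with the same
predictors and logistic form (`fit_logistic()`).  Because refitted
models must not be judged on their training data,
`finetune_and_validate()` evaluates each imputed dataset by
leave-one-out cross-validation: each patient is predicted by a model
fit on the other $n-1$, and the C-index is computed over the $n$
out-of-sample predictions.  The "multiple data splits" of the
validation design are exactly this LOOCV scheme; no additional random
train/test layer is added.

The within-dataset uncertainty of that LOOCV C-index comes from a
bootstrap nested cross-validation (BCCV): for each of $B = 25$
bootstrap resamples, every original observation occurring in the
resample is predicted by a model fit on the resample with *all* copies
of that observation deleted, and a C-index is computed over the
resample's predicted values, originals entering with their bootstrap
multiplicity — so each resample C-index mimics a leave-one-original-out
cross-validation of that bootstrap sample.  The SD of the $B$ C-indices
is the within-dataset SD.  The multiplicity-weighted evaluation set is
essential: it reproduces the full sampling variability of the
statistic, and in our Monte-Carlo checks it tracks the true
cohort-to-cohort SD of the LOOCV C-index within the expected
conservative margin, whereas evaluating each resample on all $n$
originals unweighted understates the SD several-fold (only the model
fits would vary, not the evaluation outcomes).

Coefficient SEs per dataset are the SDs of coefficient estimates over
$B$ bootstrap refits (with `M = 20, B = 25`, 500 fits in total);
coefficients and C-indices are then pooled across imputed datasets by
Rubin's rules.  Calibration deciles and the low/intermediate/high risk
strata are computed on the LOOCV (out-of-sample) predicted
probabilities averaged over the M datasets — honest predictions, not
in-sample ones.

Numerical care: logistic fits go through iteratively reweighted least
squares (`glm.fit`); a non-converged or separated fit (leave-one-out
subsets of small cohorts do occasionally separate) is refit with a
small L2 penalty, $10^{-4}$ on the slopes and none on the intercept,
and the event is flagged in the report's log.  A bootstrap resample
with a single outcome class is redrawn, up to 100 times, and logged.
All randomness in `run_validation()` derives from one seed (per-dataset
streams at `seed + m`), so two runs with identical input and
configuration produce byte-identical `report.json`.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* the validation
pipeline assumes, not any real patient population.  Baseline predictors
are drawn from pragmatic marginal families matched to the published
summaries of inception cohorts by median/spread or prevalence, not by
shape: a zero-truncated negative binomial joint count (median ≈ 3),
log-normal ESR (median ≈ 20 mm/h), scaled-beta VAS scores, and
indicator prevalences such as morning stiffness ≈ 0.60, ANA ≈ 0.50,
HLA-B27 ≈ 0.09, ankle arthritis ≈ 0.40, with JIA-category frequencies
typical of western cohorts.  Joint-site indicators, the joint count,
and stiffness load on a single weak latent severity factor — the
correlation structure among sites is not recoverable from published
tables, so one factor with modest loadings (0.35 on the count, 0.5 on
site logits) is used and documented here.

Outcomes are generated from known logistic truth models (defaults: the
published Nordic non-remission model, whose mean risk over these
marginals lands near the ~80 % non-remission rate seen in practice; a
fine-tuned severe-course reference set; the published disability
model), so generator truth is available as an oracle downstream.  An
optional `target_prevalence` shifts a truth model's intercept by
bisection on a Monte-Carlo draw of $10^5$ patients until the mean
probability matches the target within 0.2 percentage points.

Missingness masks predictor cells (never outcomes) at a configurable
rate, 0.10 by default.  MCAR masks every predictor cell uniformly; the
MAR mechanism makes the laboratory values more often missing when the
physician global assessment is low — mimicking tests ordered only when
clinically indicated — with weights normalised to preserve the overall
rate.  The complete pre-masking table is returned alongside, so tests
can compare against truth.

What passing tests on these cohorts does *not* show: robustness to the
messiness of real registry data — informative missingness beyond the
one MAR mechanism, measurement error, visit-timing heterogeneity,
cluster-derived outcome labels, or site effects.  The generator also
draws each patient independently; there is no longitudinal structure.

## Problem sizes and test design

The test suite verifies each stage against an independent oracle:
brute-force pair counting for the C-index, pROC for DeLong variances,
closed forms for Rubin pooling and the logit, and generator truth for
imputation, coefficient recovery and discrimination.  The heavier
checks run at sizes chosen to keep Monte-Carlo noise well inside the
asserted tolerances while remaining desk-scale: 200 replicate cohorts
of n = 2000 for the chance anchor; 20 seeds of (n = 2000, M = 5,
B = 25) for coefficient-recovery coverage; 200 regenerated n = 300
cohorts against five BCCV runs for the SE comparison; n = 5000 for
calibration tightness; a 400 000-draw oracle for the generating model's
large-sample AUC.

## Limitations

* The fine-tuned coefficient sets are shipped as reference constants
  for scoring; reproducing them would require the original
  access-restricted cohort data.
* The imputer offers no predictive-mean-matching variant and no
  imputation diagnostics; continuous draws assume normal residuals.
* The C-index SE for un-tuned models is DeLong's; if a validation
  design calls for a different analytic SE (Hanley–McNeil, bootstrap),
  compute it from `roc_points()`/resampling directly.
* LOOCV and BCCV refit the model $O(n)$ and $O(nB)$ times per dataset;
  at cohort sizes in the tens of thousands a k-fold scheme would be
  preferable to LOOCV, and is not provided here.
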