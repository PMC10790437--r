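---
title: "Discovering plasma sncRNA signatures of biomarker status and AD conversion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sncsig methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

`sncsig` implements a discovery pipeline for plasma small non-coding
RNA (sncRNA) biomarkers in mild cognitive impairment (MCI) cohorts.
Two endpoints are handled jointly:

* **Biomarker (ATN) positivity** — a matched case-control contrast
  between A+(T|N)+ patients (CSF amyloid-positive plus tau- or
  neurodegeneration-positive) and A-T-N- controls, 1:1 matched by sex.
* **Conversion to Alzheimer's disease** — a right-censored
  time-to-event outcome over follow-up from enrolment.

The method chain is: low-count filtering, outlier exclusion,
imputation, depth/composition normalization and per-feature
z-standardization; a negative-binomial differential-expression
screen with Benjamini–Hochberg correction; univariate conditional
logistic and Cox screens; elastic-net penalized conditional-logistic
and Cox regression with cross-validated hyperparameter search;
100-iteration stability selection with an occurrence threshold;
weighted-score construction; and a nested Cox model comparison of the
resulting scores against conventional risk factors and biomarker
status.

## Models

### Conditional logistic regression and its pair-difference reduction

For 1:1 matched pairs, conditioning on the pair removes the per-pair
intercept and the conditional likelihood for pair $i$ with case
covariates $x_i^{(1)}$ and control covariates $x_i^{(0)}$ is

$$L(\beta) = \prod_i \frac{e^{\beta' x_i^{(1)}}}{e^{\beta' x_i^{(1)}} + e^{\beta' x_i^{(0)}}}
           = \prod_i \frac{1}{1 + e^{-\beta' d_i}}, \qquad d_i = x_i^{(1)} - x_i^{(0)}.$$

This is exactly intercept-free logistic regression on the within-pair
differences with outcome fixed at 1.  The unpenalized fitter verifies
this equivalence numerically against `stats::glm.fit` on every fit
(deviance agreement to 1e-8), and the penalized version applies the
elastic-net penalty to the same loss:

$$\min_\beta \tfrac1n \sum_i \log(1 + e^{-\beta' d_i})
  + \lambda\left(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right),$$

solved by cyclic coordinate descent with soft-thresholding on a fixed
quadratic majorization (curvature bound 1/4), refreshed in an outer
loop until the largest coefficient change falls below 1e-7.  Because
sex is the matching factor it cancels in $d_i$ and never enters the
matched models; an unconditional logistic sensitivity analysis that
adjusts for sex explicitly is provided.

### Penalized and unpenalized Cox regression

Conversion hazards are modelled with Cox proportional hazards.  The
unpenalized fitter maximizes the Efron-corrected partial likelihood by
Newton–Raphson with step-halving (gradient max-norm tolerance 1e-8,
at most 50 iterations) and reports standard errors from the observed
information; monotone likelihoods (perfect risk separation) are
flagged.  The penalized fitter minimizes minus the (1/n-scaled)
Breslow partial log-likelihood plus the elastic-net penalty by
coordinate descent on the iteratively reweighted least-squares working
problem, the standard approach for penalized Cox models.  Both solvers
are validated against dense grid-search oracles, KKT conditions,
finite-difference gradients, `survival::coxph`, and `glmnet`.

### Hyperparameter search

The search follows a repeated 90/10 split design: in each of
`tuning_reps` repetitions (default 20) the data are split with pairs
kept intact (matched endpoint) or stratified by event status
(survival endpoint), features are re-standardized on the training
portion, and a 10-fold cross-validation inside the training set picks
$\lambda$ for every $\alpha$ on the grid (0.10 to 1.00 in 0.05 steps;
pure ridge excluded).  CV uses binomial deviance for the matched
endpoint and the Verweij–van Houwelingen partial-likelihood deviance
for the survival endpoint.  Candidates are then scored on the held-out
10% by AUC or Harrell's C.

Two deliberate conventions, both documented as this package's own
design choices:

* **The 1-SE lambda rule (default).**  Within each CV curve the
  largest $\lambda$ whose mean deviance is within one standard error
  of the minimum is selected (`lambda_rule = "min"` restores the
  minimizer).  With ~95 pairs and ~208 features the deviance
  minimizer is noisy, and on signal-free data it frequently selects
  small penalties whose spuriously stable features would then survive
  stability selection; the 1-SE rule is the standard parsimony
  convention for exactly this situation and restores clean null
  behaviour (empty or near-empty null signatures).
* **A 1-SE parsimony band on alpha.**  The held-out score of a single
  repetition has a standard error of roughly 0.05–0.10 at these test
  sizes, so a raw argmax over $\alpha$ is decided by noise.  The
  selected $\alpha$ is the largest one whose mean held-out score lies
  within one standard error of the best — the natural extension of
  the tie-break-towards-sparsity rule.  $\lambda^\ast$ is the median
  of the per-repetition selections at $\alpha^\ast$.

### Stability selection and signatures

With $(\alpha^\ast, \lambda^\ast)$ fixed, 100 iterations each draw a
fresh 90% training subsample (whole pairs, or subjects stratified by
event), re-standardize within the subsample, and refit.  A feature's
occurrence is the number of iterations with a non-zero coefficient;
the signature keeps features with occurrence at or above 90 ("selected
in at least 90 of 100"; a strict-greater flag is available).  Weights
are mean coefficients over the selecting iterations with percentile
95% CIs.  The signature score for sample $j$ is
$\sum_g w_g x_{gj}$ over signature features of standardized
expression, z-transformed to mean 0, SD 1.

Signature performance (AUC or Harrell's C) is reported with two
labelled uncertainty estimates: a subject-level bootstrap percentile
CI (default 1000 resamples) and the spread of the 100 per-iteration
held-out metrics ("iteration spread") — the latter is typically much
narrower because it reflects Monte-Carlo variation of the procedure,
not sampling variation of subjects.

### Nested model evaluation

Four Cox models are compared: M1, conventional risk factors (age,
sex, BMI, APOE ε4, smoking as former/current dummies, education, four
medication flags, baseline MMSE); M2 = M1 + biomarker positivity;
M3 = M1 + signature score; M4 = M2 + score.  Likelihood-ratio tests
are reported only for genuinely nested pairs (M1→M2, M1→M3, M2→M4,
M3→M4).  M2 and M3 are not nested; a bootstrap difference in
C-statistics with a percentile CI is reported instead.  Hazard ratios
for the score are per z-score (per SD, since the score is
standardized).  C-statistics are apparent (in-sample) with
subject-bootstrap CIs computed at fixed linear predictors; the
cross-validated alternative is intentionally out of scope of the
model table.

## The synthetic cohort generator

Because the motivating cohort is not public, every stage is exercised
on synthetic cohorts with the statistical structure the analysis
assumes:

* **Counts.**  Negative binomial in the mean–dispersion
  parameterization $\mathrm{Var} = \mu + \phi\mu^2$, with per-feature
  baselines log-normal (meanlog 3.1, sdlog 1.5 — chosen so that about
  17% of 250 features fall below the 1000-total-read filter, leaving
  roughly 208), per-feature dispersions uniform on [0.05, 0.5],
  per-sample depths log-normal (log-SD 0.35), and three latent factors
  with sparse loadings (SD 0.3) inducing the cross-feature correlation
  that motivates an elastic net over the lasso.
* **Design.**  1:1 sex-matched pairs; covariates drawn conditionally
  on case status to reproduce the descriptive gradients of the
  emulated cohort (cases older, more APOE ε4, lower MMSE, fewer
  antidepressants/anxiolytics).  The default sampling route generates
  a superpopulation and selects a sex-matched biomarker-negative
  control per case, preserving the nested selection logic; a direct
  fast path draws pairs immediately.
* **Planted effects.**  Case-associated features shift mean
  log-expression by `effect_log_or` (default 0.8) standard deviations
  of log-expression, half up for cases and half down for controls,
  with random signs.  Hazard-associated features enter the conversion
  hazard through their realized standardized log-expression with
  coefficient `effect_log_hr` (default 0.5) each; biomarker positivity
  itself carries a direct log hazard ratio (default 1.9, calibrated
  once by pilot simulation so the realized case/control event gradient
  is steep, as in the emulated cohort), plus fixed age and APOE ε4
  effects so adjusted models are non-trivial.  Planted features are
  drawn among features abundant enough to survive the low-count
  filter; otherwise the planted signal could vanish in preprocessing
  by construction and recovery tests would measure the filter, not
  the method.
* **Censoring.**  Event times are exponential given the subject's
  hazard; censoring is the minimum of a 5-year administrative horizon
  and a uniform dropout time (lower bound 0.25 years so follow-up is
  strictly positive).
* **Artifacts.**  A configurable fraction of cells is set missing
  (default 1%) and a disjoint fraction (default 0.5%) is multiplied
  by 10.  With low-dispersion features a ×10 cell is guaranteed to
  exceed the |z| > 3 masking rule; at the upper end of the default
  dispersion range (φ ≈ 0.5, log-scale SD ≈ 0.7) the shift is ≈ 3.3
  SDs and a cell that started below its feature mean can stay inside
  the band — outlier masking then catches most but not every injected
  cell.  Tests of the per-realization masking guarantee therefore use
  a low-dispersion configuration.

What a green test does **not** establish: the generator plants
independent Gaussian-ish latent structure and clean exponential
hazards; real sncRNA data have heavier tails, batch structure, and
non-proportional hazards that are out of scope here.  Event rates
among biomarker-negative controls are higher than the emulated
cohort's 5.3% because the planted per-feature hazard effects act as a
marginal frailty; the case/control gradient direction and steepness
are preserved, the absolute control rate is not.

## Preprocessing conventions

* The stated order is respected: filtering, then outlier exclusion,
  then imputation.  Outlier masking works on the per-feature z scale,
  records its reference statistics on first use so that re-masking is
  idempotent, and converts outliers to missing values that the imputer
  then fills.
* Normalization is median-of-ratios (reference features are those
  with no zero count; a "poscounts"-style fallback engages, with a
  warning, when none exists).  Gene length is deliberately not
  adjusted: every downstream statistic is per-feature, and a
  within-feature constant cancels in z-scores.
* log2 with pseudo-count 0.5 before standardization (configurable);
  0.5 avoids log(0) with minimal distortion at these count sizes.
* Imputation defaults to a round-robin tree-ensemble (missForest
  style) built on randomized regression trees, iterated to a relative
  tolerance of 1e-3 or 10 sweeps; tree seeds are fixed across sweeps
  so the iteration is a deterministic fixed point.  `knn` and
  `feature_median` are provided as fast deterministic alternatives
  and are used by the test suite where imputation quality is not the
  question.
* Standardization is recomputed inside every training
  subsample/fold and applied to the held-out part; the global-scaling
  alternative would leak held-out information into tuning.

## Numerical choices

* Coordinate-descent convergence: largest coefficient change below
  1e-7, with iteration caps (30 quadratic refreshes × 50 sweeps);
  near the saturated end of a p > n path the pair-difference loss is
  separable and coefficients would otherwise grow without bound.
  The lambda path stops at 5% of the data-derived maximum (the usual
  p > n convention).
* Newton solvers use step-halving and flag |β| > 15 as
  separation/monotone likelihood.
* Ties in the argmax over hyperparameters resolve towards the larger
  lambda, then the larger alpha (sparser models).
* Degenerate bootstrap resamples (single class, zero events) are
  redrawn and counted.
* In the null-calibration tests an "empty or near-empty" signature is
  defined once as at most 2% of retained features (4 of ~208).
* All randomness flows from explicit seeds; internal seed derivation
  stays below 2^31, and RNG state is restored after every seeded
  operation.

## Known limitations

* The differential-expression stage is a plain NB Wald test with
  method-of-moments dispersions (optionally trend-shrunk); the full
  DESeq2 machinery (empirical-Bayes dispersion shrinkage, Cook's
  filtering, independent filtering) is intentionally not reproduced —
  in this pipeline the DE screen is descriptive and does not feed the
  signatures.
* Conditional-logistic fitting is exact only for 1:1 matching (the
  pair-difference reduction); general m:n matched sets are out of
  scope.
* The C-statistic CIs at fixed linear predictors ignore coefficient
  estimation uncertainty; refitting inside the bootstrap would
  roughly double the cost and is left to the user.
* Generator covariates are drawn independently conditional on case
  status with the emulated cohort's marginal gradients; eleven
  quasi-independent weak discriminators jointly separate case status
  more sharply than correlated real covariates would, so fully
  adjusted conditional-logistic fits on matched pairs are often
  near-separated (flagged, with inflated standard errors).  The
  adjusted screen is exposed and honest about this; power checks in
  the test suite use the unadjusted matched screen.
* On signal-free data a handful of features can be spuriously stable
  across heavily overlapping 90% subsamples; the 1-SE rule keeps this
  rare but cannot eliminate it, and with correlated features a null
  feature proxying a planted one can reach high occurrence counts.
  Occurrence counts should therefore be read jointly with weights and
  CIs, not as significance statements.
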