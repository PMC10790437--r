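# sncsig

Discovery of plasma small non-coding RNA (sncRNA) signatures in
matched nested case-control cohorts of mild cognitive impairment
(MCI): one signature for CSF biomarker (ATN) positivity, one for
conversion to Alzheimer's disease (AD), and an evaluation of what
each adds to conventional risk prediction.

## Who this is for

Biostatisticians and computational biologists who have (or want to
simulate) a features-by-samples sncRNA count matrix plus a per-sample
phenotype table from a 1:1 sex-matched case-control design with
right-censored follow-up, and who want a tested, reproducible
implementation of the full discovery chain rather than a one-off
analysis script.

## The method

1. **Preprocessing** — drop transcripts with fewer than 1000 total
   reads; median-of-ratios size factors; `log2(count/sf + 0.5)`;
   per-feature z-scores; mask cells beyond |z| > 3 as missing; impute
   with a round-robin tree-ensemble (missForest style), k-NN, or
   feature medians.
2. **Univariate screens** — negative-binomial Wald differential
   expression with Benjamini–Hochberg FDR; conditional logistic
   regression (matched pairs; exact pair-difference reduction) and
   Cox proportional hazards (Efron ties) per feature.
3. **Penalized signatures** — elastic-net conditional-logistic and
   Cox regression by coordinate descent,
   `lambda * (alpha * ||b||_1 + (1-alpha)/2 * ||b||_2^2)` with alpha
   searched over 0.10–1.00 in 0.05 steps; repeated 90/10 splits with
   tenfold CV inside the training set; 100-iteration stability
   selection keeping features selected in at least 90 iterations;
   weights = mean coefficients with percentile CIs.
4. **Scores and evaluation** — per-sample weighted sums, z-scaled;
   nested Cox models M1 (conventional risk factors), M2 (+ ATN),
   M3 (+ score), M4 (+ score + ATN); hazard ratios per SD of score,
   Harrell's C with bootstrap CIs, likelihood-ratio tests for nested
   pairs and a bootstrap difference in C for the non-nested pair.
5. **Synthetic cohorts** — a generator with planted case-associated
   and hazard-associated feature sets, NB counts
   (`Var = mu + phi mu^2`), latent-factor correlation, depth
   variation, missingness/outlier injection, and a truth record, so
   every stage is testable without patient data.

See `vignettes/sncsig-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(sncsig)

cfg <- sim_config(n_pairs = 95, n_features = 250, seed = 3)
cohort <- generate_cohort(cfg)
counts <- inject_artifacts(cohort$counts, cfg)
expr   <- preprocess_counts(counts, seed = 3)

ec  <- enet_config(tuning_reps = 2, alpha_grid = c(0.3, 0.6, 0.9),
                   n_lambda = 15, bootstrap_reps = 200, seed = 3)
sig <- fit_signature(expr, cohort$pheno, endpoint = "ad", config = ec)
print(sig)

score  <- compute_score(expr, sig)
models <- model_sequence(cohort$pheno, score, boot_reps = 200, seed = 3)
print(models$table[, c("model_id", "hr_per_sd", "hr_p", "c_statistic",
                       "lrt_p_vs_m1", "lrt_p_vs_m2")])
```

Output from this exact script:

```
<snc_signature> endpoint=ad alpha=0.90 lambda=0.087026
  15/198 features selected (threshold 90/100)
  c_statistic = 0.8198 (95% CI 0.7736-0.8638)
  model_id hr_per_sd         hr_p c_statistic  lrt_p_vs_m1  lrt_p_vs_m2
1       M1        NA           NA   0.6899119           NA           NA
2       M2  2.884131 4.234062e-04   0.7076183 3.033804e-04           NA
3       M3  4.429646 1.144611e-22   0.8364660 7.060509e-27           NA
4       M4  4.383570 2.444534e-21   0.8400981           NA 1.284547e-24
```

Reading it: this simulated cohort plants 15 hazard-associated
features; hyperparameter search settled on alpha 0.90, stability
selection kept 15 of 198 retained features (7 planted ones plus
correlated proxies), and the resulting conversion signature reaches a
C-statistic of 0.82 on its own.  In the nested Cox comparison,
biomarker positivity improves the conventional model (M2 vs M1,
likelihood-ratio p = 3e-4), the signature score improves it far more
(M3: HR 4.4 per SD, C 0.69 -> 0.84), and the score remains strongly
associated with conversion after ATN adjustment (M4) — the pattern
that distinguishes a hazard signature with information beyond
biomarker status.

## Command line

```sh
Rscript inst/cli/sncsig.R simulate --seed 1 --out out/
Rscript inst/cli/sncsig.R run-all  --seed 1 --out out/ --pairs 95
```
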