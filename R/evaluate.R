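#' Weighted signature score
#'
#' Per-sample weighted sum of the signature features' standardized
#' expression, using the stability-selection mean coefficients as
#' weights (positive or negative), then z-transformed to mean 0,
#' SD 1 over the scored cohort.
#'
#' @param expr an [snc_expr()] (standardized).
#' @param signature an `snc_signature`; its `mean_coef` supplies the
#'   weights.
#' @param weights named numeric vector of weights, as an alternative
#'   to `signature`.
#' @return named per-sample numeric vector (mean 0, SD 1).
#' @export
compute_score <- function(expr, signature = NULL, weights = NULL) {
  stopifnot(inherits(expr, "snc_expr"))
  w <- weights %||% signature$mean_coef
  if (is.null(w) || !length(w)) stopf("no weights: empty signature")
  if (all(w == 0)) stopf("degenerate signature: all weights zero")
  missing <- setdiff(names(w), rownames(expr$values))
  if (length(missing))
    stopf("signature feature(s) absent from expression matrix: %s",
          paste(missing, collapse = ", "))
  raw <- drop(crossprod(expr$values[names(w), , drop = FALSE], w))
  if (sd(raw) < 1e-12) stopf("degenerate signature: constant score")
  setNames((raw - mean(raw)) / sd(raw), colnames(expr$values))
}

#' Harrell's concordance index
#'
#' `C = (concordant + 0.5 * risk-tied) / comparable` over subject
#' pairs (i, j) in which the subject with the shorter follow-up time
#' had the event; pairs tied on an event time are not comparable.
#'
#' @param time follow-up times.
#' @param event binary event indicators.
#' @param risk_score higher values mean higher predicted risk.
#' @return concordance in `[0, 1]`, or `NA` with zero comparable
#'   pairs.
#' @export
harrell_c <- function(time, event, risk_score) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk_score) == n)
  ev <- which(event == 1)
  if (!length(ev)) return(NA_real_)
  # comparable (i, j): i had the event and failed first — t_i < t_j,
  # or t_i == t_j with j censored; event-event time ties excluded
  ti <- time[ev]; ri <- risk_score[ev]
  lt <- outer(ti, time, `<`)
  tie_cens <- outer(ti, time, `==`) & matrix(event == 0, length(ev), n, byrow = TRUE)
  comp_m <- lt | tie_cens
  diag_idx <- cbind(seq_along(ev), ev)
  comp_m[diag_idx] <- FALSE
  comp <- sum(comp_m)
  if (comp == 0) return(NA_real_)
  conc <- sum(comp_m & outer(ri, risk_score, `>`)) +
    0.5 * sum(comp_m & outer(ri, risk_score, `==`))
  conc / comp
}

#' Area under the ROC curve
#'
#' Mann-Whitney U formulation with ties counted 0.5.
#'
#' @param labels binary labels (0/1).
#' @param score classifier score, larger for the positive class.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(labels, score) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval of a metric
#'
#' Subject-level resampling with replacement; degenerate resamples
#' (the metric returns `NA`, e.g. single-class or zero-event draws)
#' are redrawn and counted in the `n_redrawn` attribute.
#'
#' @param metric_fn function of a data frame returning a scalar.
#' @param data data frame, one row per subject.
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return list with `estimate`, `ci95_low`, `ci95_high`.
#' @export
bootstrap_ci <- function(metric_fn, data, reps = 1000, seed = 1) {
  if (reps < 100) stopf("reps must be >= 100")
  est <- metric_fn(data)
  n <- nrow(data)
  vals <- numeric(reps)
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(reps)) {
      v <- NA_real_
      for (try in 1:10) {
        v <- metric_fn(data[sample.int(n, n, replace = TRUE), , drop = FALSE])
        if (!is.na(v)) break
        redrawn <- redrawn + 1L
      }
      vals[b] <- v
    }
  })
  out <- list(estimate = est,
              ci95_low = unname(quantile(vals, 0.025, na.rm = TRUE)),
              ci95_high = unname(quantile(vals, 0.975, na.rm = TRUE)))
  attr(out, "n_redrawn") <- redrawn
  attr(out, "boot_values") <- vals
  out
}

lrt_p <- function(fit_big, fit_small, df) {
  stat <- 2 * (fit_big$loglik - fit_small$loglik)
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Nested Cox model comparison for a signature score
#'
#' Fits the four models of the signature evaluation: M1 conventional
#' risk factors (age, sex, BMI, APOE e4, smoking, education, the four
#' medication flags, baseline MMSE); M2 = M1 + biomarker (ATN)
#' positivity; M3 = M1 + signature score; M4 = M2 + signature score.
#' Reports the hazard ratio per z-score of the score (per SD, since
#' the score is standardized) or of the ATN indicator, the apparent
#' Harrell C-statistic with a subject-bootstrap percentile 95% CI,
#' and likelihood-ratio tests for the nested pairs M1->M2, M1->M3,
#' M2->M4, M3->M4.  M2 vs M3 are not nested: a bootstrap difference
#' in C with percentile CI is reported instead of an LRT.
#'
#' @param pheno phenotype table.
#' @param score a [compute_score()] vector aligned with
#'   `pheno$sample_id`.
#' @param boot_reps bootstrap replicates for the C-statistic CIs.
#' @param seed integer seed.
#' @return list with `table` (one row per model) and
#'   `delta_c_m2_m3` (estimate and percentile CI).
#' @export
model_sequence <- function(pheno, score, boot_reps = 1000, seed = 1) {
  stopifnot(length(score) == nrow(pheno))
  Z1 <- build_covariates(pheno, include_sex = TRUE)
  if (!all(complete.cases(Z1))) stopf("covariates incomplete")
  designs <- list(
    M1 = Z1,
    M2 = cbind(Z1, atn = pheno$atn_case),
    M3 = cbind(Z1, score = score),
    M4 = cbind(Z1, atn = pheno$atn_case, score = score))
  fits <- lapply(names(designs), function(nm) {
    f <- fit_cox(designs[[nm]], pheno$followup_years, pheno$ad_event)
    if (!f$converged && !f$flagged) stopf("model %s did not converge", nm)
    f
  })
  names(fits) <- names(designs)

  c_with_ci <- function(X, fit, tag) {
    risk <- drop(X %*% fit$coef)
    bc <- bootstrap_ci(function(d) harrell_c(d$time, d$event, d$risk),
                       data.frame(time = pheno$followup_years,
                                  event = pheno$ad_event, risk = risk),
                       reps = boot_reps, seed = child_seed(seed, tag))
    bc
  }
  cs <- Map(c_with_ci, designs, fits, seq_along(fits))

  term_of <- c(M1 = NA, M2 = "atn", M3 = "score", M4 = "score")
  row <- function(nm, lrt1 = NA, lrt2 = NA, lrt3 = NA) {
    f <- fits[[nm]]
    trm <- term_of[[nm]]
    est <- if (is.na(trm)) NA_real_ else f$coef[[trm]]
    sev <- if (is.na(trm)) NA_real_ else f$se[[trm]]
    data.frame(model_id = nm,
               hr_per_sd = exp(est),
               hr_ci_low = exp(est - qnorm(0.975) * sev),
               hr_ci_high = exp(est + qnorm(0.975) * sev),
               hr_p = if (is.na(trm)) NA_real_ else 2 * pnorm(-abs(est / sev)),
               c_statistic = cs[[nm]]$estimate,
               c_ci_low = cs[[nm]]$ci95_low,
               c_ci_high = cs[[nm]]$ci95_high,
               loglik = f$loglik,
               n_par = length(f$coef),
               lrt_p_vs_m1 = lrt1, lrt_p_vs_m2 = lrt2, lrt_p_vs_m3 = lrt3,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("M1"),
    row("M2", lrt1 = lrt_p(fits$M2, fits$M1, 1)),
    row("M3", lrt1 = lrt_p(fits$M3, fits$M1, 1)),
    row("M4", lrt2 = lrt_p(fits$M4, fits$M2, 1),
        lrt3 = lrt_p(fits$M4, fits$M3, 1)))

  # non-nested M2 vs M3: bootstrap difference in C (fixed risk scores)
  r2 <- drop(designs$M2 %*% fits$M2$coef)
  r3 <- drop(designs$M3 %*% fits$M3$coef)
  dc <- bootstrap_ci(function(d) harrell_c(d$time, d$event, d$r3) -
                       harrell_c(d$time, d$event, d$r2),
                     data.frame(time = pheno$followup_years,
                                event = pheno$ad_event, r2 = r2, r3 = r3),
                     reps = boot_reps, seed = child_seed(seed, 99))
  list(table = tab,
       delta_c_m2_m3 = list(estimate = dc$estimate,
                            ci95_low = dc$ci95_low,
                            ci95_high = dc$ci95_high),
       fits = fits)
}
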