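test_that("conditional logistic regression matches its closed forms and oracle", {
  # no information: identical case/control covariates
  D0 <- matrix(0, 8, 1)
  f0 <- fit_conditional_logistic(D0, verify_equivalence = FALSE)
  expect_equal(unname(f0$coef), 0)
  expect_false(is.finite(f0$se[[1]]))
  # null log-likelihood is n * log(1/2)
  expect_equal(f0$loglik, 8 * log(0.5))

  # 5 hand-constructed pairs, differences {+1,+1,+1,-1,+1}: the fit
  # matches a 1-D maximizer of the conditional likelihood to 1e-6
  d <- matrix(c(1, 1, 1, -1, 1), 5, 1)
  f1 <- fit_conditional_logistic(d)
  expect_lt(abs(f1$coef[[1]] - oracle_clogit_1d(c(1, 1, 1, -1, 1))), 1e-6)

  # separation is flagged with non-finite CI
  dsep <- matrix(rep(1, 6), 6, 1)
  fs <- fit_conditional_logistic(dsep, verify_equivalence = FALSE)
  expect_true(fs$flagged)
  expect_false(is.finite(fs$se[[1]]))
})

test_that("conditional logistic equals pair-difference logistic and survival::clogit", {
  library(survival)
  set.seed(12)
  n_pairs <- 60
  X <- cbind(a = rnorm(2 * n_pairs), b = rnorm(2 * n_pairs))
  pairs <- rep(seq_len(n_pairs), each = 2)
  case <- rep(c(1, 0), n_pairs)
  X[case == 1, "a"] <- X[case == 1, "a"] + 0.5
  fit <- fit_conditional_logistic(X, pairs, case)
  # deviance equivalence with the no-intercept logistic on differences
  expect_lt(fit$equiv_dev_diff, 1e-8)
  # agreement with the survival package's conditional likelihood fit
  cl <- survival::clogit(case ~ a + b + strata(pairs),
                         data = data.frame(X, pairs = pairs, case = case))
  expect_equal(unname(fit$coef), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cl)))), tolerance = 1e-6)
})

test_that("Cox regression matches derivatives, reference fits, and flags degeneracies", {
  library(survival)
  # constant covariate: no contrast, beta = 0
  Xc <- matrix(1, 10, 1)
  tt <- 1:10; ev <- rep(1, 10)
  expect_equal(unname(fit_cox(Xc, tt, ev)$coef), 0)

  # two subjects, monotone likelihood flagged
  f2 <- fit_cox(matrix(c(1, 0), 2, 1), c(1, 2), c(1, 1))
  expect_true(f2$flagged)

  # 20-subject data: analytic gradient matches central finite
  # differences at 3 random points, to 1e-6
  set.seed(13)
  X <- matrix(rnorm(20 * 3), 20, 3)
  tt <- rexp(20, exp(0.4 * X[, 1])); ev <- rbinom(20, 1, 0.7)
  ev[1] <- 1
  for (k in 1:3) {
    b <- rnorm(3, sd = 0.4)
    for (ties in c("efron", "breslow")) {
      pl <- cox_partial_loglik(b, X, tt, ev, ties)
      g_fd <- fd_grad(function(bb) cox_partial_loglik(bb, X, tt, ev, ties)$loglik, b)
      expect_lt(max(abs(pl$gradient - g_fd)), 1e-6)
    }
  }

  # estimate matches survival::coxph to 1e-4 (with tied times, Efron)
  set.seed(14)
  n <- 90
  X <- matrix(rnorm(n * 4), n, 4)
  tt <- ceiling(rexp(n, exp(0.5 * X[, 1] - 0.4 * X[, 2])) * 8) / 8
  ev <- rbinom(n, 1, 0.65)
  fit <- fit_cox(X, tt, ev)
  ref <- coxph(Surv(tt, ev) ~ X, ties = "efron")
  expect_lt(max(abs(fit$coef - coef(ref))), 1e-4)
  expect_lt(max(abs(fit$se - sqrt(diag(vcov(ref))))), 1e-4)

  # without ties, Efron and Breslow agree to 1e-8
  tt2 <- tt + runif(n, 0, 1e-4)
  fe <- fit_cox(X, tt2, ev, "efron")
  fb <- fit_cox(X, tt2, ev, "breslow")
  expect_lt(max(abs(fe$coef - fb$coef)), 1e-8)
})

test_that("univariate screens are calibrated at null and detect planted features", {
  # null cohort: ~5% of features at p < 0.05, none surviving FDR
  ch0 <- toy_cohort(seed = 31, n_pairs = 60, n_features = 50, effect = 0)
  ex0 <- preprocess_counts(ch0$counts, impute_method = "feature_median")
  scr0 <- run_univariate_screen(ex0, ch0$pheno, "clogit")
  expect_lt(mean(scr0$p < 0.05, na.rm = TRUE), 0.15)
  expect_lte(sum(scr0$padj < 0.05, na.rm = TRUE), 1)

  # planted features: detected by the matched-pairs screen, with the
  # unconditional sensitivity model agreeing in sign.  The unadjusted
  # screen carries the power here: the full covariate adjustment set
  # discriminates case status so well in this generator that adjusted
  # conditional fits are near-separated (large SEs) — see the methods
  # vignette.
  hits <- signs <- integer(0)
  for (s in 1:3) {
    ch <- toy_cohort(seed = 40 + s, n_pairs = 80, n_features = 40, effect = 0.9)
    ex <- preprocess_counts(ch$counts, impute_method = "feature_median")
    scr <- run_univariate_screen(ex, ch$pheno, "clogit", adjusted = FALSE)
    sens <- run_univariate_screen(ex, ch$pheno, "logistic_sensitivity",
                                  adjusted = FALSE)
    planted <- ch$truth$atn_features
    planted <- planted[planted %in% scr$feature_id]
    i <- match(planted, scr$feature_id)
    hits <- c(hits, scr$padj[i] < 0.05)
    signs <- c(signs, sign(scr$estimate[i]) == sign(sens$estimate[i]))
  }
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
  expect_gte(mean(signs, na.rm = TRUE), 0.95)
})
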