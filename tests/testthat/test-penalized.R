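test_that("pair-difference elastic net matches KKT conditions and the grid oracle", {
  set.seed(50)
  D <- matrix(rnorm(10 * 2), 10, 2)
  D[, 1] <- D[, 1] + 0.8
  # lambda at or above lambda_max gives an exactly zero solution
  for (a in c(0.4, 1)) {
    lmx <- clogit_lambda_max(D, a)
    expect_equal(unname(clogit_enet(D, a, lmx * 1.0001)), c(0, 0))
    expect_gt(max(abs(clogit_enet(D, a, lmx * 0.9))), 0)
  }
  # dense grid oracle on 2-feature problems, several (alpha, lambda)
  for (a in c(0.5, 1)) {
    for (l in c(0.02, 0.1)) {
      beta <- clogit_enet(D, a, l)
      orc <- oracle_clogit_enet_grid(D, a, l)
      expect_lt(max(abs(beta - orc$beta)), 4e-3)      # grid resolution
      expect_lte(orc$obj(beta), orc$value + 1e-7)     # at least as good
      grad <- sncsig:::clogit_enet_grad(beta, D)
      expect_lt(sncsig:::kkt_residual(beta, grad, a, l), 1e-5)
    }
  }
  # duplicated feature with a ridge component: symmetric coefficients
  Dd <- cbind(D[, 1], D[, 1])
  bd <- clogit_enet(Dd, 0.6, 0.05, tol = 1e-10)
  expect_equal(bd[[1]], bd[[2]], tolerance = 1e-6)
})

test_that("penalized Cox matches KKT, the grid oracle, and the unpenalized limit", {
  set.seed(51)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2)
  tt <- rexp(n, exp(0.7 * X[, 1])); ev <- rbinom(n, 1, 0.7); ev[1:3] <- 1
  for (a in c(0.5, 1)) {
    lmx <- cox_lambda_max(X, tt, ev, a)
    expect_equal(unname(cox_enet(X, tt, ev, a, lmx * 1.0001)), c(0, 0))
    for (l in c(0.02, 0.08)) {
      beta <- cox_enet(X, tt, ev, a, l)
      orc <- oracle_cox_enet_grid(X, tt, ev, a, l)
      expect_lt(max(abs(beta - orc$beta)), 4e-3)
      expect_lte(orc$obj(beta), orc$value + 1e-7)
      grad <- sncsig:::cox_enet_grad(beta, X, tt, ev)
      expect_lt(sncsig:::kkt_residual(beta, grad, a, l), 1e-5)
    }
  }
  # lambda -> 0 with a single feature converges to the unpenalized fit
  x1 <- X[, 1, drop = FALSE]
  b0 <- cox_enet(x1, tt, ev, 1, 1e-7)
  bu <- fit_cox(x1, tt, ev, ties = "breslow")$coef
  expect_lt(abs(b0 - bu), 1e-3)
})

test_that("penalized solvers agree with glmnet on moderate problems", {
  library(glmnet); library(survival)
  set.seed(52)
  n <- 100; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  tt <- rexp(n, exp(0.5 * X[, 1] - 0.5 * X[, 2])); ev <- rbinom(n, 1, 0.6)
  ev[which.max(tt)] <- 0
  for (a in c(0.65, 0.9)) {
    for (l in c(0.03, 0.08)) {
      bm <- cox_enet(X, tt, ev, a, l)
      bg <- as.numeric(coef(glmnet(X, Surv(tt, ev), family = "cox",
                                   alpha = a, lambda = l,
                                   standardize = FALSE, thresh = 1e-12)))
      expect_lt(max(abs(bm - bg)), 1e-5)
    }
  }
})

test_that("hyperparameter search honours its contract", {
  ch <- toy_cohort(seed = 60, n_pairs = 40, n_features = 25, effect = 1.0)
  ex <- preprocess_counts(ch$counts, impute_method = "feature_median")
  # degenerate grid: a single (alpha, lambda) candidate is returned
  # unchanged (one repetition; the lambda path is data-derived, so one
  # candidate per repetition)
  cfg1 <- enet_config(alpha_grid = 0.5, n_lambda = 1, tuning_reps = 1,
                      cv_folds = 4, bootstrap_reps = 100, seed = 60)
  tu <- tune_hyperparameters(ex, ch$pheno, "atn", cfg1)
  expect_equal(tu$alpha_star, 0.5)
  expect_equal(length(unique(tu$trace$lambda)), 1)
  expect_equal(tu$lambda_star, tu$trace$lambda[1])
  # trace covers reps x alphas
  cfg2 <- enet_config(alpha_grid = c(0.5, 1), n_lambda = 8, tuning_reps = 2,
                      cv_folds = 4, bootstrap_reps = 100, seed = 60)
  tu2 <- tune_hyperparameters(ex, ch$pheno, "atn", cfg2)
  expect_equal(nrow(tu2$trace), 4)
  expect_true(tu2$alpha_star %in% c(0.5, 1))
  # config validation
  expect_error(enet_config(alpha_grid = c(0, 0.5)), "ridge")
  expect_error(enet_config(occurrence_threshold = 200), "exceeds")
  expect_error(enet_config(train_fraction = 1), "train_fraction")
})

test_that("stability selection separates planted signal from noise", {
  ch <- toy_cohort(seed = 61, n_pairs = 70, n_features = 40, effect = 1.0)
  ex <- preprocess_counts(ch$counts, impute_method = "feature_median")
  cfg <- enet_config(alpha_grid = 0.9, n_lambda = 10, tuning_reps = 2,
                     cv_folds = 5, stability_iters = 60,
                     occurrence_threshold = 54, bootstrap_reps = 100,
                     seed = 61)
  tu <- tune_hyperparameters(ex, ch$pheno, "atn", cfg)
  sig <- stability_select(ex, ch$pheno, "atn", tu$alpha_star, tu$lambda_star, cfg)
  occ <- sig$occurrences
  planted <- intersect(ch$truth$atn_features, names(occ))
  nulls <- setdiff(names(occ), planted)
  # planted occurrences stochastically dominate the null occurrences
  mw <- wilcox.test(occ[planted], occ[nulls], alternative = "greater",
                    exact = FALSE)
  expect_lt(mw$p.value, 0.01)
  # selected set contract
  expect_true(all(sig$occurrences[sig$selected_features] >=
                    cfg$occurrence_threshold))
  expect_true(all(sig$mean_coef != 0))
  expect_true(all(sig$selected_features %in% names(occ)))
  # performance block present with both CI flavours
  expect_true(!is.null(sig$performance))
  expect_true(sig$performance$ci95_low <= sig$performance$ci95_high)
  expect_true(is.finite(sig$performance$iteration_spread$mean))

  # occurrence_threshold = 0: every feature ever selected is kept,
  # with well-defined weights
  cfg0 <- enet_config(alpha_grid = 0.9, n_lambda = 10, tuning_reps = 2,
                      cv_folds = 5, stability_iters = 20,
                      occurrence_threshold = 0, bootstrap_reps = 100,
                      seed = 61)
  sig0 <- stability_select(ex, ch$pheno, "atn", tu$alpha_star,
                           tu$lambda_star, cfg0)
  expect_setequal(sig0$selected_features,
                  names(which(sig0$occurrences > 0)))
  expect_true(all(is.finite(sig0$mean_coef)))
})

test_that("warm-started paths keep the active set loosely monotone in lambda", {
  # logged diagnostic, asserted only loosely: averaged over the path,
  # the active set does not grow as lambda increases
  set.seed(62)
  D <- matrix(rnorm(50 * 30), 50, 30)
  D[, 1:3] <- D[, 1:3] + 0.6
  lmx <- clogit_lambda_max(D, 1)
  path <- sncsig:::lambda_path(lmx, 15, 0.05)
  b <- rep(0, 30)
  sizes <- vapply(path, function(l) {
    b <<- clogit_enet(D, 1, l, beta_init = b)
    sum(b != 0)
  }, numeric(1))
  # path is decreasing in lambda, so sizes should tend upwards
  expect_gte(mean(diff(sizes) >= 0), 0.6)
})
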