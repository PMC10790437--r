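test_that("signature scores are the z-scaled weighted sums", {
  v <- matrix(c(1, 2, 3, 4,
                0, 1, 0, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ex <- snc_expr(v)
  w <- c(g1 = 0.5, g2 = -0.2)
  raw <- 0.5 * v[1, ] - 0.2 * v[2, ]
  expect_equal(unname(compute_score(ex, weights = w)),
               unname((raw - mean(raw)) / sd(raw)))
  # a single-feature signature with weight 1 on a standardized feature
  # reproduces that feature
  z <- (v[1, ] - mean(v[1, ])) / sd(v[1, ])
  exz <- snc_expr(matrix(z, 1, 4, dimnames = list("g1", names(z))))
  expect_equal(unname(compute_score(exz, weights = c(g1 = 1))), unname(z))
  # degenerate and missing-feature errors
  expect_error(compute_score(ex, weights = c(g1 = 0, g2 = 0)), "zero")
  expect_error(compute_score(ex, weights = c(nope = 1)), "nope")
})

test_that("Harrell's C matches brute force, closed cases, and survival", {
  library(survival)
  # worked 6-subject set
  tt <- 1:6; ev <- c(1, 1, 0, 1, 0, 1); rk <- 6:1
  expect_equal(harrell_c(tt, ev, rk), oracle_harrell_c(tt, ev, rk))
  # perfect ordering (risk opposite to time), no censoring -> C = 1
  expect_equal(harrell_c(1:8, rep(1, 8), 8:1), 1)
  # constant risk: all ties -> 0.5
  expect_equal(harrell_c(1:8, rep(1, 8), rep(2, 8)), 0.5)
  # no comparable pairs -> NA
  expect_true(is.na(harrell_c(c(1, 1), c(1, 1), c(2, 1))))
  # property: equality with the all-pairs oracle (and the survival
  # package) on random censored datasets with ties, n <= 50
  set.seed(70)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    tt <- sample(1:12, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    rk <- sample(seq_len(6), n, replace = TRUE) + rnorm(n, 0, 1e-9)
    c1 <- harrell_c(tt, ev, rk)
    expect_equal(c1, oracle_harrell_c(tt, ev, rk))
    if (!is.na(c1) && sum(ev) > 0) {
      c2 <- concordance(Surv(tt, ev) ~ rk, reverse = TRUE)$concordance
      expect_equal(c1, unname(c2), tolerance = 1e-12)
    }
  }
})

test_that("ROC AUC matches enumeration and trapezoidal integration", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_true(is.na(roc_auc(c(1, 1), c(0.2, 0.4))))
  set.seed(71)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    sc <- sample(seq_len(8), n, replace = TRUE) / 8
    expect_equal(roc_auc(lab, sc), oracle_auc_trapezoid(lab, sc),
                 tolerance = 1e-10)
  }
  # independence at large n: close to 1/2
  set.seed(72)
  expect_lt(abs(roc_auc(rbinom(4000, 1, 0.5), rnorm(4000)) - 0.5), 0.05)
})

test_that("bootstrap CIs behave and approximately cover", {
  d <- data.frame(x = rnorm(30))
  cst <- bootstrap_ci(function(dd) 1.0, d, reps = 100, seed = 1)
  expect_equal(cst$ci95_low, 1.0)
  expect_equal(cst$ci95_high, 1.0)
  # estimate inside the CI across seeds
  set.seed(73)
  for (s in 1:5) {
    dd <- data.frame(x = rnorm(60, 2))
    bc <- bootstrap_ci(function(z) mean(z$x), dd, reps = 200, seed = s)
    expect_gte(bc$estimate, bc$ci95_low - 1e-12)
    expect_lte(bc$estimate, bc$ci95_high + 1e-12)
  }
  expect_error(bootstrap_ci(function(z) 1, d, reps = 10), ">= 100")

  # coverage of the C-statistic CI at n = 190: simulate a population
  # with known concordance and count how often the percentile CI
  # covers it (tolerance band per the stated +/- 4%)
  set.seed(74)
  n_pop <- 5000
  risk_pop <- rnorm(n_pop)
  t_pop <- rexp(n_pop, exp(0.8 * risk_pop))
  cens <- quantile(t_pop, 0.6)
  ev_pop <- as.integer(t_pop <= cens)
  t_obs <- pmin(t_pop, cens)
  c_true <- harrell_c(t_obs, ev_pop, risk_pop)
  cover <- vapply(1:150, function(s) {
    idx <- sample(n_pop, 190)
    dd <- data.frame(time = t_obs[idx], event = ev_pop[idx],
                     risk = risk_pop[idx])
    bc <- bootstrap_ci(function(z) harrell_c(z$time, z$event, z$risk),
                       dd, reps = 150, seed = s)
    bc$ci95_low <= c_true && c_true <= bc$ci95_high
  }, logical(1))
  expect_gte(mean(cover), 0.89)
  expect_lte(mean(cover), 1.00)
})

test_that("the nested model sequence respects nesting and detects a hazard score", {
  ch <- toy_cohort(seed = 80, n_pairs = 60, n_features = 30, effect = 1.2)
  ex <- preprocess_counts(ch$counts, impute_method = "feature_median")
  # a score built from the planted hazard features with true signs
  w <- ch$truth$ad_effects[ch$truth$ad_features %in% rownames(ex$values)]
  sc <- compute_score(ex, weights = w)
  ms <- model_sequence(ch$pheno, sc, boot_reps = 100, seed = 80)
  tab <- ms$table
  # M4 nests M2 and M3: its log-likelihood can never be lower
  expect_gte(tab$loglik[4], tab$loglik[2] - 1e-9)
  expect_gte(tab$loglik[4], tab$loglik[3] - 1e-9)
  expect_equal(tab$n_par, c(12, 13, 13, 14))
  # the hazard score improves on the conventional model
  expect_lt(tab$lrt_p_vs_m1[3], 0.05)
  expect_gt(tab$c_statistic[3], tab$c_statistic[1])
  # LRT p-values only for nested pairs; M2-vs-M3 reported as delta-C
  expect_true(is.na(tab$lrt_p_vs_m2[2]))
  expect_true(all(is.finite(unlist(ms$delta_c_m2_m3))))
})

test_that("a pure-noise score yields uniform nested-test p-values", {
  pvals <- vapply(1:20, function(s) {
    ch <- toy_cohort(seed = 900 + s, n_pairs = 50, n_features = 20,
                     effect = 0)
    set.seed(1900 + s)
    noise <- setNames(rnorm(nrow(ch$pheno)), ch$pheno$sample_id)
    noise <- (noise - mean(noise)) / sd(noise)
    ms <- model_sequence(ch$pheno, noise, boot_reps = 100, seed = s)
    ms$table$lrt_p_vs_m2[4]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})
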