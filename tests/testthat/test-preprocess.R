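make_counts <- function(m, ...) snc_counts(m, ...)

test_that("low-count filter keeps exactly the features at or above the threshold", {
  m <- rbind(a = rep(100, 5), b = c(996, 1, 1, 1, 1), c = rep(2400, 5))
  colnames(m) <- paste0("s", 1:5)
  # row sums: 500, 1000, 12000
  expect_equal(rowSums(m), c(a = 500, b = 1000, c = 12000))
  kept <- filter_low_expression(make_counts(m), 1000)
  expect_identical(rownames(kept$counts), c("b", "c"))
  # boundary: 999 removed, 1000 retained
  m2 <- rbind(x = c(999, 0), y = c(1000, 0))
  colnames(m2) <- c("s1", "s2")
  expect_identical(rownames(filter_low_expression(make_counts(m2))$counts), "y")
  expect_error(filter_low_expression(make_counts(matrix(0, 3, 4))), "total reads")
})

test_that("median-of-ratios size factors match the hand-computed example", {
  m <- matrix(c(100, 10, 200, 20), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  sf <- size_factors_median_of_ratios(make_counts(m))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # symmetry: identical samples get identical factors
  m3 <- matrix(rpois(40, 60) + 1, 10, 4)
  m3[, 2] <- m3[, 1]
  sf3 <- size_factors_median_of_ratios(make_counts(m3))
  expect_equal(sf3[[1]], sf3[[2]])
  # scale equivariance: doubling one sample doubles its factor
  m4 <- m3
  m4[, 3] <- 2 * m3[, 1]
  sf4 <- size_factors_median_of_ratios(make_counts(m4))
  expect_equal(sf4[[3]] / sf4[[1]], 2, tolerance = 1e-12)
  # poscounts fallback warns when no zero-free feature exists
  m5 <- matrix(c(0, 5, 7, 0), 2, 2)
  expect_warning(size_factors_median_of_ratios(make_counts(m5)), "poscounts")
})

test_that("normalization standardizes features and preserves within-feature order", {
  set.seed(4)
  m <- matrix(rpois(300, 80) + 1, 15, 20)
  ex <- normalize_and_standardize(make_counts(m))
  expect_lt(max(abs(rowMeans(ex$values))), 1e-8)
  expect_lt(max(abs(apply(ex$values, 1, sd) - 1)), 1e-8)
  # monotone transform: sample ordering preserved per feature
  sf <- size_factors_median_of_ratios(make_counts(m))
  norm <- sweep(m, 2, sf, `/`)
  for (g in c(1, 7, 15))
    expect_identical(order(norm[g, ]), order(ex$values[g, ]))
  # degenerate: identical samples, equal factors -> constant features warn
  mc <- matrix(5L, 4, 6)
  expect_warning(normalize_and_standardize(make_counts(mc)), "constant")
})

test_that("outlier masking follows the per-feature z rule and is idempotent", {
  # hand example: feature {0,0,0,0,10}: mean 2, sd sqrt(20), z(10) = 8/4.472 = 1.789 < 3
  v <- matrix(c(0, 0, 0, 0, 10), 1, 5)
  ex <- snc_expr(v)
  expect_equal(sum(mask_outliers(ex, 3)$mask), 0)
  expect_equal(sum(mask_outliers(ex, 1.5)$mask), 1) # 1.789 > 1.5
  # all equal: zero variance, warning, no masking
  expect_warning(mo <- mask_outliers(snc_expr(matrix(1, 2, 5))), "constant")
  expect_equal(sum(mo$mask), 0)
  # infinite threshold: identity
  set.seed(9)
  exr <- snc_expr(matrix(rnorm(200), 10, 20))
  expect_equal(mask_outliers(exr, Inf)$mask, exr$mask)
  # idempotence via recorded reference statistics
  m1 <- mask_outliers(exr, 2)
  m2 <- mask_outliers(m1, 2)
  expect_identical(m1$mask, m2$mask)
})

test_that("imputation honours its contracts", {
  set.seed(10)
  v <- matrix(rnorm(120), 6, 20,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:20)))
  ex <- snc_expr(v)
  # no masked cells: identity on values
  expect_equal(impute_missing(ex, "feature_median")$values, v)
  # feature_median fills the observed median
  v2 <- v; v2[3, 5] <- NA
  ex2 <- snc_expr(v2)
  got <- impute_missing(ex2, "feature_median")$values[3, 5]
  expect_equal(got, median(v2[3, -5], na.rm = TRUE))
  # unmasked cells are never modified, any method
  for (mth in c("feature_median", "knn", "iterative_forest")) {
    out <- impute_missing(ex2, mth, seed = 1)
    expect_equal(out$values[!ex2$mask], v2[!ex2$mask])
    expect_false(anyNA(out$values))
  }
  # an entirely-missing feature is an error naming the feature
  v3 <- v; v3[2, ] <- NA
  expect_error(impute_missing(snc_expr(v3), "feature_median"), "f2")
})

test_that("tree-ensemble imputation is at least as accurate as feature medians", {
  # paired comparison over 10 seeds on cohorts with 5% missingness
  # (matrix size reduced from the default cohort to keep the suite fast)
  rmse_f <- rmse_m <- numeric(10)
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_pairs = 50, n_features = 80,
                      missing_frac = 0.05, outlier_frac = 0)
    ch <- generate_cohort(cfg, method = "direct")
    cc <- inject_artifacts(ch$counts, cfg)
    ex <- suppressWarnings(normalize_and_standardize(filter_low_expression(cc)))
    full <- suppressWarnings(normalize_and_standardize(ch$counts))
    fullv <- full$values[rownames(ex$values), ]
    idx <- which(ex$mask)
    rf <- impute_missing(ex, "iterative_forest", seed = s)
    md <- impute_missing(ex, "feature_median")
    rmse_f[s] <- sqrt(mean((rf$values[idx] - fullv[idx])^2))
    rmse_m[s] <- sqrt(mean((md$values[idx] - fullv[idx])^2))
  }
  expect_lte(mean(rmse_f), mean(rmse_m))
})

test_that("the chain is deterministic and scale-invariant", {
  cfg <- sim_config(seed = 21, n_pairs = 40, n_features = 60)
  ch <- generate_cohort(cfg, method = "direct")
  cc <- inject_artifacts(ch$counts, cfg)
  e1 <- preprocess_counts(cc, seed = 5)
  e2 <- preprocess_counts(cc, seed = 5)
  expect_identical(e1, e2)

  # multiplying one sample's counts rescales its size factor relative
  # to every other sample by exactly that constant (the absolute
  # factors all carry a common c^(1/n) from the geometric means, as in
  # any median-of-ratios scheme), and leaves standardized values of
  # zero-free features unchanged when no pseudo-count distorts the log
  kept <- filter_low_expression(ch$counts)
  zero_free <- rowSums(kept$counts == 0) == 0
  m <- kept$counts[zero_free, , drop = FALSE]
  ms <- m; ms[, 7] <- 4 * ms[, 7]
  exa <- normalize_and_standardize(make_counts(m), pseudo_count = 0)
  exb <- normalize_and_standardize(make_counts(ms), pseudo_count = 0)
  rel_a <- exa$size_factors / exa$size_factors[[1]]
  rel_b <- exb$size_factors / exb$size_factors[[1]]
  expect_equal(rel_b[[7]] / rel_a[[7]], 4, tolerance = 1e-9)
  expect_equal(rel_b[-7], rel_a[-7], tolerance = 1e-9)
  expect_lt(max(abs(exb$values - exa$values)), 1e-6)
})
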