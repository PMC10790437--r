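#' Elastic-net tuning and stability-selection configuration
#'
#' Defaults follow the discovery procedure: alpha from 0.10 to 1.00 in
#' 0.05 steps (pure ridge excluded), lambda on an automatic decreasing
#' path, tenfold cross-validation inside a 20-repetition 90/10
#' train-test loop, 100 stability-selection iterations with the
#' "selected in at least 90 of 100" rule, and a 1000-iteration
#' evaluation loop for the performance CI.
#'
#' @param alpha_grid elastic-net mixing values in (0, 1].
#' @param n_lambda points on the automatic lambda path.
#' @param lambda_min_ratio smallest lambda as a fraction of the
#'   data-derived `lambda_max`.
#' @param cv_folds folds of the inner cross-validation.
#' @param tuning_reps repetitions of the split+CV procedure.
#' @param train_fraction training share of each split.
#' @param stability_iters subsampling iterations.
#' @param occurrence_threshold minimum number of iterations a feature
#'   must be selected in to enter the signature.
#' @param strict_greater require strictly more than
#'   `occurrence_threshold` occurrences instead of at least.
#' @param bootstrap_reps resampled evaluations for the performance CI.
#' @param lambda_rule `"1se"` (largest lambda within one standard
#'   error of the cross-validation minimum; the usual parsimony
#'   convention for sparse screens) or `"min"`.
#' @param seed integer seed.
#' @return a validated list of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = seq(0.10, 1.00, by = 0.05),
                        n_lambda = 30, lambda_min_ratio = 0.05,
                        cv_folds = 10, tuning_reps = 20,
                        train_fraction = 0.90,
                        stability_iters = 100, occurrence_threshold = 90,
                        strict_greater = FALSE,
                        bootstrap_reps = 1000,
                        lambda_rule = c("1se", "min"), seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  cfg <- as.list(environment())
  if (any(cfg$alpha_grid <= 0 | cfg$alpha_grid > 1))
    stopf("alpha_grid must lie in (0, 1] (pure ridge excluded)")
  if (cfg$occurrence_threshold > cfg$stability_iters)
    stopf("occurrence_threshold exceeds stability_iters")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (cfg$cv_folds < 2) stopf("cv_folds must be >= 2")
  structure(cfg, class = "enet_config")
}

#' Elastic-net penalized conditional logistic regression
#'
#' Minimizes, over the 1:1 pair-difference reduction (no intercept),
#' `(1/n) sum_i log(1 + exp(-b'd_i)) +
#'  lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`
#' by cyclic coordinate descent with soft-thresholding on a quadratic
#' majorization; convergence when the largest coefficient change falls
#' below `tol`.
#'
#' @param D pairs x features matrix of within-pair differences.
#' @param alpha elastic-net mixing in (0, 1].
#' @param lambda penalty strength (>= 0).
#' @param beta_init warm-start coefficients.
#' @param tol coordinate-change convergence tolerance.
#' @return named coefficient vector.
#' @export
clogit_enet <- function(D, alpha, lambda, beta_init = NULL, tol = 1e-7) {
  D <- as.matrix(D)
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (lambda < 0) stopf("lambda must be >= 0")
  if (lambda == 0 && qr(D)$rank < ncol(D))
    warnf("lambda = 0 with collinear features: solution not unique")
  b0 <- beta_init %||% rep(0, ncol(D))
  beta <- .cd_binomial_pairdiff(D, alpha, lambda, as.numeric(b0), tol = tol)
  setNames(as.numeric(beta), colnames(D))
}

#' Smallest lambda that zeroes all coefficients (pair-difference loss)
#' @param D pair-difference matrix.
#' @param alpha elastic-net mixing.
#' @return scalar `lambda_max`.
#' @export
clogit_lambda_max <- function(D, alpha) {
  max(abs(colMeans(as.matrix(D)) / 2)) / alpha
}

#' Elastic-net penalized Cox regression
#'
#' Minimizes `-(1/n) * Cox partial log-likelihood (Breslow ties) +
#' lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)` by coordinate
#' descent on the iteratively reweighted least-squares working
#' problem.
#'
#' @param X subjects x features matrix.
#' @param time positive follow-up times.
#' @param event binary event indicators.
#' @inheritParams clogit_enet
#' @return named coefficient vector.
#' @export
cox_enet <- function(X, time, event, alpha, lambda, beta_init = NULL,
                     tol = 1e-7) {
  X <- as.matrix(X)
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (lambda < 0) stopf("lambda must be >= 0")
  if (any(time <= 0)) stopf("time must be positive")
  if (sum(event) < 1) stopf("at least one event required")
  o <- order(time)
  b0 <- beta_init %||% rep(0, ncol(X))
  beta <- .cd_cox(X[o, , drop = FALSE], time[o], as.integer(event[o]),
                  alpha, lambda, as.numeric(b0), tol = tol)
  setNames(as.numeric(beta), colnames(X))
}

#' Smallest lambda that zeroes all coefficients (Cox loss)
#' @inheritParams cox_enet
#' @return scalar `lambda_max`.
#' @export
cox_lambda_max <- function(X, time, event, alpha) {
  X <- as.matrix(X)
  o <- order(time)
  si <- .cox_score_info0(time[o], as.integer(event[o]),
                         rep(0, length(time)))
  u <- si$resid
  max(abs(drop(crossprod(X[o, , drop = FALSE], u)) / nrow(X))) / alpha
}

# decreasing log-spaced lambda path
lambda_path <- function(lambda_max, n_lambda, min_ratio) {
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = n_lambda))
}

# lambda choice from a folds x path CV-deviance matrix: the
# deviance-minimizing lambda ("min") or the largest lambda within one
# standard error of the minimum ("1se"); the path is decreasing, so
# the first qualifying index is the largest lambda
pick_lambda <- function(path, dev, rule) {
  md <- colMeans(dev)
  li <- which.min(md)
  if (rule == "1se") {
    se <- apply(dev, 2, sd) / sqrt(nrow(dev))
    li <- which(md <= md[li] + se[li])[1]
  }
  path[li]
}

# elastic-net KKT residual; grad is the gradient of the unpenalized
# (1/n-scaled) loss at beta
kkt_residual <- function(beta, grad, alpha, lambda) {
  active <- beta != 0
  r_active <- if (any(active))
    max(abs(grad[active] + lambda * (1 - alpha) * beta[active] +
              lambda * alpha * sign(beta[active]))) else 0
  r_zero <- if (any(!active))
    max(0, max(abs(grad[!active])) - lambda * alpha) else 0
  max(r_active, r_zero)
}

clogit_enet_grad <- function(beta, D) {
  eta <- drop(D %*% beta)
  -drop(crossprod(D, 1 - plogis(eta))) / nrow(D)
}

cox_enet_grad <- function(beta, X, time, event) {
  o <- order(time)
  Xo <- X[o, , drop = FALSE]
  eta <- drop(Xo %*% beta)
  si <- .cox_score_info0(time[o], as.integer(event[o]), eta)
  -drop(crossprod(Xo, si$resid)) / nrow(X)
}

# standardize columns on training rows, apply to all rows; constant
# columns pass through unchanged
standardize_cols_train <- function(M, train_idx) {
  mu <- colMeans(M[train_idx, , drop = FALSE])
  s <- apply(M[train_idx, , drop = FALSE], 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  sweep(sweep(M, 2, mu), 2, s, `/`)
}

# Breslow partial log-likelihood value only (matches the penalized
# solver); avoids the O(p^2) Hessian of cox_partial_loglik
cox_pl_breslow <- function(beta, X, time, event) {
  o <- order(time)
  eta <- drop(X[o, , drop = FALSE] %*% beta)
  eta <- eta - mean(eta)
  time <- time[o]; event <- event[o]
  ex <- exp(eta)
  rs <- rev(cumsum(rev(ex)))            # risk-set sums at each sorted index
  first <- !duplicated(time)            # index of first subject per tied time
  riskmap <- rs[first][match(time, time[first])]
  sum(eta[event == 1]) - sum(log(riskmap[event == 1]))
}

# event-stratified fold assignment; refolds until every fold contains
# an event (up to 20 attempts, logged)
stratified_folds <- function(event, k, seed) {
  n <- length(event)
  for (try in seq_len(20)) {
    f <- with_seed(child_seed(seed, try), {
      f <- integer(n)
      for (lev in unique(event)) {
        idx <- which(event == lev)
        f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(j) sum(event[f != j]) > 0, logical(1)))
    if (ok) return(structure(f, refolds = try - 1L))
  }
  stopf("could not build folds with events in every training set")
}

#' Cross-validated (alpha, lambda) search
#'
#' For each of `tuning_reps` repetitions the data are split 90/10
#' (pairs kept intact for the matched endpoint; event-stratified for
#' the survival endpoint) and features are re-standardized on the
#' training portion.  Within the training set a `cv_folds`-fold
#' cross-validation picks lambda for every alpha on the grid
#' (binomial deviance for the matched endpoint;
#' Verweij-van Houwelingen partial-likelihood deviance for the
#' survival endpoint); each candidate (alpha, lambda(alpha)) is then
#' scored by AUC or Harrell's C on the held-out 10%.  The selected
#' alpha maximizes the mean held-out score over repetitions (ties go
#' to the larger alpha, i.e. the sparser model) and the selected
#' lambda is the median of the per-repetition lambdas at that alpha
#' (ties to the larger lambda).
#'
#' @param expr an [snc_expr()] (standardized features x samples).
#' @param pheno phenotype table.
#' @param endpoint `"atn"` (matched case-control) or `"ad"`
#'   (conversion survival).
#' @param config an [enet_config()].
#' @return list with `alpha_star`, `lambda_star` and the full
#'   `trace` data frame (rep, alpha, lambda, heldout score).
#' @export
tune_hyperparameters <- function(expr, pheno, endpoint = c("atn", "ad"),
                                 config = enet_config()) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(config, "enet_config"))
  E <- t(expr$values)                    # samples x features
  trace <- list()
  for (r in seq_len(config$tuning_reps)) {
    srep <- child_seed(config$seed, 7700 + r)
    if (endpoint == "atn") {
      trace[[r]] <- tune_rep_atn(E, pheno, config, srep, r)
    } else {
      trace[[r]] <- tune_rep_ad(E, pheno, config, srep, r)
    }
  }
  trace <- do.call(rbind, trace)
  agg <- tapply(trace$score, trace$alpha, mean, na.rm = TRUE)
  nrep <- tapply(trace$score, trace$alpha, function(s) sum(!is.na(s)))
  sds <- tapply(trace$score, trace$alpha, sd, na.rm = TRUE)
  best <- which.max(agg)
  # parsimony band: the largest alpha whose mean held-out score is
  # within one standard error of the best (exact-tie rule when only
  # one repetition is available)
  band <- if (nrep[best] > 1 && is.finite(sds[best]))
    sds[best] / sqrt(nrep[best]) else 1e-12
  ok <- agg >= agg[best] - band
  alpha_star <- max(as.numeric(names(agg))[ok])
  lams <- trace$lambda[trace$alpha == alpha_star]
  lambda_star <- max(median(lams), min(lams)) # median; degenerate-safe
  list(alpha_star = alpha_star, lambda_star = lambda_star, trace = trace)
}

tune_rep_atn <- function(E, pheno, config, srep, r) {
  pair_ids <- unique(pheno$pair_id)
  np <- length(pair_ids)
  test_pairs <- with_seed(srep, sample(pair_ids, max(1, round((1 - config$train_fraction) * np))))
  train_s <- which(!pheno$pair_id %in% test_pairs)
  Es <- standardize_cols_train(E, train_s)
  D <- pair_differences(Es, pheno$pair_id, pheno$atn_case)
  Dtr <- D[setdiff(pair_ids, test_pairs), , drop = FALSE]
  folds <- with_seed(child_seed(srep, 1),
                     sample(rep(seq_len(config$cv_folds), length.out = nrow(Dtr))))
  out <- lapply(seq_along(config$alpha_grid), function(ai) {
    a <- config$alpha_grid[ai]
    path <- lambda_path(clogit_lambda_max(Dtr, a), config$n_lambda,
                        config$lambda_min_ratio)
    dev <- matrix(0, config$cv_folds, length(path))
    for (k in seq_len(config$cv_folds)) {
      Dk <- Dtr[folds != k, , drop = FALSE]
      Dv <- Dtr[folds == k, , drop = FALSE]
      b <- rep(0, ncol(Dk))
      for (li in seq_along(path)) {
        b <- clogit_enet(Dk, a, path[li], beta_init = b)
        eta <- drop(Dv %*% b)
        dev[k, li] <- 2 * sum(log1p(exp(-eta)))
      }
    }
    lam <- pick_lambda(path, dev, config$lambda_rule)
    bfull <- clogit_enet(Dtr, a, lam)
    sc <- roc_auc(pheno$atn_case[-train_s],
                  drop(Es[-train_s, , drop = FALSE] %*% bfull))
    data.frame(rep = r, alpha = a, lambda = lam, score = sc)
  })
  do.call(rbind, out)
}

tune_rep_ad <- function(E, pheno, config, srep, r) {
  n <- nrow(E)
  ev <- pheno$ad_event
  test_s <- with_seed(srep, {
    unlist(lapply(unique(ev), function(lev) {
      idx <- which(ev == lev)
      sample(idx, max(1, round((1 - config$train_fraction) * length(idx))))
    }))
  })
  train_s <- setdiff(seq_len(n), test_s)
  Es <- standardize_cols_train(E, train_s)
  Xtr <- Es[train_s, , drop = FALSE]
  ttr <- pheno$followup_years[train_s]; etr <- ev[train_s]
  folds <- stratified_folds(etr, config$cv_folds, child_seed(srep, 2))
  out <- lapply(seq_along(config$alpha_grid), function(ai) {
    a <- config$alpha_grid[ai]
    path <- lambda_path(cox_lambda_max(Xtr, ttr, etr, a), config$n_lambda,
                        config$lambda_min_ratio)
    dev <- matrix(0, config$cv_folds, length(path))
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      b <- rep(0, ncol(Xtr))
      for (li in seq_along(path)) {
        b <- cox_enet(Xtr[tr, , drop = FALSE], ttr[tr], etr[tr], a, path[li],
                      beta_init = b)
        # Verweij-van Houwelingen: pl(all) - pl(without fold)
        dev[k, li] <- -2 * (cox_pl_breslow(b, Xtr, ttr, etr) -
                              cox_pl_breslow(b, Xtr[tr, , drop = FALSE],
                                             ttr[tr], etr[tr]))
      }
    }
    lam <- pick_lambda(path, dev, config$lambda_rule)
    bfull <- cox_enet(Xtr, ttr, etr, a, lam)
    sc <- harrell_c(pheno$followup_years[test_s], ev[test_s],
                    drop(Es[test_s, , drop = FALSE] %*% bfull))
    data.frame(rep = r, alpha = a, lambda = lam, score = sc)
  })
  do.call(rbind, out)
}

#' Stability selection at fixed hyperparameters
#'
#' Runs `stability_iters` iterations, each drawing a fresh 90%
#' training subsample (whole pairs for the matched endpoint;
#' event-stratified subjects for the survival endpoint),
#' re-standardizing features within the subsample, and fitting the
#' penalized model at `(alpha_star, lambda_star)`.  Per-feature
#' occurrence counts the iterations with a non-zero coefficient; the
#' signature keeps features at or above `occurrence_threshold` (or
#' strictly above with `strict_greater`).  Weights are the mean
#' coefficient over selecting iterations with a percentile 95% CI.
#' Performance of the weighted signature score is evaluated in a
#' `bootstrap_reps`-iteration resampled loop (subject bootstrap,
#' percentile CI); the spread of the per-iteration held-out metric is
#' reported alongside, labelled `iteration_spread`.
#'
#' @inheritParams tune_hyperparameters
#' @param alpha_star,lambda_star fixed hyperparameters.
#' @return an object of class `snc_signature`.
#' @export
stability_select <- function(expr, pheno, endpoint = c("atn", "ad"),
                             alpha_star, lambda_star,
                             config = enet_config()) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(config, "enet_config"))
  E <- t(expr$values)
  feats <- colnames(E)
  p <- length(feats)
  iters <- config$stability_iters
  occ <- integer(p)
  coefs <- matrix(NA_real_, iters, p, dimnames = list(NULL, feats))
  held <- numeric(iters)

  for (b in seq_len(iters)) {
    sit <- child_seed(config$seed, 31000 + b)
    if (endpoint == "atn") {
      pair_ids <- unique(pheno$pair_id)
      tr_pairs <- with_seed(sit, sample(pair_ids, round(config$train_fraction * length(pair_ids))))
      tr_s <- which(pheno$pair_id %in% tr_pairs)
      Es <- standardize_cols_train(E, tr_s)
      D <- pair_differences(Es, pheno$pair_id, pheno$atn_case)
      beta <- clogit_enet(D[tr_pairs, , drop = FALSE], alpha_star, lambda_star)
      ho <- setdiff(seq_len(nrow(E)), tr_s)
      held[b] <- roc_auc(pheno$atn_case[ho],
                         drop(Es[ho, , drop = FALSE] %*% beta))
    } else {
      ev <- pheno$ad_event
      tr_s <- with_seed(sit, {
        sort(unlist(lapply(unique(ev), function(lev) {
          idx <- which(ev == lev)
          sample(idx, round(config$train_fraction * length(idx)))
        })))
      })
      Es <- standardize_cols_train(E, tr_s)
      beta <- cox_enet(Es[tr_s, , drop = FALSE],
                       pheno$followup_years[tr_s], ev[tr_s],
                       alpha_star, lambda_star)
      ho <- setdiff(seq_len(nrow(E)), tr_s)
      held[b] <- harrell_c(pheno$followup_years[ho], ev[ho],
                           drop(Es[ho, , drop = FALSE] %*% beta))
    }
    nz <- beta != 0
    occ <- occ + nz
    coefs[b, nz] <- beta[nz]
  }

  thr <- config$occurrence_threshold
  sel <- if (config$strict_greater) occ > thr else occ >= thr
  sel <- sel & occ > 0L   # threshold 0 means "ever selected"
  selected <- feats[sel]
  if (!length(selected))
    warnf("no feature reached the %s%d/%d occurrence threshold: empty signature",
          if (config$strict_greater) ">" else ">=", thr, iters)
  mean_coef <- vapply(selected, function(f) mean(coefs[, f], na.rm = TRUE),
                      numeric(1))
  coef_ci <- t(vapply(selected, function(f)
    quantile(coefs[, f], c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    numeric(2)))
  if (length(selected)) colnames(coef_ci) <- c("ci_low", "ci_high")

  perf <- NULL
  if (length(selected)) {
    score <- compute_score(expr, weights = mean_coef)
    if (endpoint == "atn") {
      bc <- bootstrap_ci(function(d) roc_auc(d$label, d$score),
                         data.frame(label = pheno$atn_case, score = score),
                         reps = config$bootstrap_reps,
                         seed = child_seed(config$seed, 555))
    } else {
      bc <- bootstrap_ci(function(d) harrell_c(d$time, d$event, d$score),
                         data.frame(time = pheno$followup_years,
                                    event = pheno$ad_event, score = score),
                         reps = config$bootstrap_reps,
                         seed = child_seed(config$seed, 556))
    }
    perf <- list(metric = if (endpoint == "atn") "auc" else "c_statistic",
                 estimate = bc$estimate,
                 ci95_low = bc$ci95_low, ci95_high = bc$ci95_high,
                 ci_method = "subject_bootstrap_percentile",
                 iteration_spread = list(
                   mean = mean(held, na.rm = TRUE),
                   ci95_low = unname(quantile(held, 0.025, na.rm = TRUE)),
                   ci95_high = unname(quantile(held, 0.975, na.rm = TRUE))))
  }

  structure(list(endpoint = endpoint,
                 alpha_star = alpha_star, lambda_star = lambda_star,
                 occurrences = setNames(as.integer(occ), feats),
                 selected_features = selected,
                 mean_coef = mean_coef, coef_ci95 = coef_ci,
                 heldout_metric = held,
                 performance = perf, config = unclass(config)),
            class = "snc_signature")
}

#' @export
print.snc_signature <- function(x, ...) {
  cat(sprintf("<snc_signature> endpoint=%s alpha=%.2f lambda=%.6f\n",
              x$endpoint, x$alpha_star, x$lambda_star))
  cat(sprintf("  %d/%d features selected (threshold %d/%d)\n",
              length(x$selected_features), length(x$occurrences),
              x$config$occurrence_threshold, x$config$stability_iters))
  if (!is.null(x$performance))
    cat(sprintf("  %s = %.4f (95%% CI %.4f-%.4f)\n", x$performance$metric,
                x$performance$estimate, x$performance$ci95_low,
                x$performance$ci95_high))
  invisible(x)
}

#' Run tuning and stability selection in one call
#'
#' @inheritParams tune_hyperparameters
#' @return an `snc_signature` with the tuning trace attached.
#' @export
fit_signature <- function(expr, pheno, endpoint = c("atn", "ad"),
                          config = enet_config()) {
  endpoint <- match.arg(endpoint)
  tuned <- tune_hyperparameters(expr, pheno, endpoint, config)
  sig <- stability_select(expr, pheno, endpoint,
                          tuned$alpha_star, tuned$lambda_star, config)
  sig$tuning_trace <- tuned$trace
  sig
}
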