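#' Pair-difference matrix for 1:1 matched designs
#'
#' For each pair, case-row minus control-row of the sample-level
#' covariate matrix.  The conditional likelihood of 1:1 matched
#' logistic regression depends on the data only through these
#' differences.
#'
#' @param X samples x covariates numeric matrix.
#' @param pairs pair identifier per sample.
#' @param case binary case indicator per sample.
#' @return pairs x covariates matrix of within-pair differences.
#' @export
pair_differences <- function(X, pairs, case) {
  X <- as.matrix(X)
  ids <- unique(pairs)
  D <- matrix(NA_real_, length(ids), ncol(X),
              dimnames = list(ids, colnames(X)))
  for (i in seq_along(ids)) {
    sel <- which(pairs == ids[i])
    if (length(sel) != 2 || sum(case[sel]) != 1)
      stopf("pair %s is not a discordant 1:1 pair", ids[i])
    D[i, ] <- X[sel[case[sel] == 1], ] - X[sel[case[sel] == 0], ]
  }
  D
}

clogit_loglik <- function(beta, D) {
  eta <- drop(D %*% beta)
  -sum(log1p(exp(-eta)))
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the conditional likelihood
#' `prod_i exp(b'x_case) / (exp(b'x_case) + exp(b'x_ctrl))` by
#' Newton-Raphson with step-halving; equivalently intercept-free
#' logistic regression on within-pair differences with outcome 1.
#' The equivalence is verified numerically against `stats::glm.fit`
#' on the differences (deviance match), and standard errors come from
#' the observed information.  Separation (monotone likelihood) is
#' flagged and the CI reported as non-finite.
#'
#' @param X samples x covariates matrix (or a pre-computed
#'   pair-difference matrix with `pairs = NULL`).
#' @param pairs pair ids per sample; `NULL` if `X` already holds
#'   pair differences.
#' @param case case indicator per sample (ignored when `pairs` is
#'   `NULL`).
#' @param verify_equivalence cross-check the deviance against the
#'   pair-difference logistic fit.
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return list with `coef`, `se`, `vcov`, `loglik`, `loglik_null`
#'   (`n log 1/2`), `converged`, `flagged`, `equiv_dev_diff`.
#' @export
fit_conditional_logistic <- function(X, pairs = NULL, case = NULL,
                                     verify_equivalence = TRUE,
                                     tol = 1e-8, max_iter = 50) {
  D <- if (is.null(pairs)) as.matrix(X) else pair_differences(X, pairs, case)
  n <- nrow(D); p <- ncol(D)
  beta <- rep(0, p)
  flagged <- FALSE; conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    pr <- plogis(eta)                     # P(case first | pair)
    grad <- drop(crossprod(D, 1 - pr))
    W <- pr * (1 - pr)
    info <- crossprod(D * sqrt(W))
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) { flagged <- TRUE; break }
    ll0 <- clogit_loglik(beta, D)
    sh <- 1
    repeat {
      cand <- beta + sh * step
      if (clogit_loglik(cand, D) >= ll0 - 1e-12 || sh < 1e-6) break
      sh <- sh / 2
    }
    beta <- beta + sh * step
    if (max(abs(beta)) > 15) { flagged <- TRUE; break } # separation
  }
  eta <- drop(D %*% beta)
  pr <- plogis(eta)
  info <- crossprod(D * sqrt(pmax(pr * (1 - pr), 0)))
  vc <- tryCatch(solve(info), error = function(e) matrix(Inf, p, p))
  se <- sqrt(pmax(diag(as.matrix(vc)), 0))
  if (flagged) se[] <- Inf
  ll <- clogit_loglik(beta, D)
  equiv <- NA_real_
  if (verify_equivalence && !flagged) {
    gf <- suppressWarnings(
      stats::glm.fit(D, rep(1, n), family = stats::binomial(),
                     intercept = FALSE))
    equiv <- abs(gf$deviance - (-2 * ll))
    if (is.finite(equiv) && equiv > 1e-6)
      warnf("pair-difference equivalence check off by %.2e", equiv)
  }
  list(coef = setNames(beta, colnames(D)), se = setNames(se, colnames(D)),
       vcov = vc, loglik = ll, loglik_null = n * log(0.5),
       converged = conv, flagged = flagged, equiv_dev_diff = equiv,
       n_pairs = n)
}

#' Cox partial log-likelihood, gradient and Hessian
#'
#' Efron or Breslow handling of tied event times.  Exposed so that
#' derivative checks against finite differences are possible.
#'
#' @param beta coefficient vector.
#' @param X subjects x covariates matrix.
#' @param time positive follow-up times.
#' @param event binary event indicators.
#' @param ties `"efron"` or `"breslow"`.
#' @return list with `loglik`, `gradient`, `hessian`.
#' @export
cox_partial_loglik <- function(beta, X, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  o <- order(time)
  X <- X[o, , drop = FALSE]; time <- time[o]; event <- event[o]
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  ex <- exp(eta)
  ll <- 0; grad <- rep(0, p); hess <- matrix(0, p, p)
  ut <- unique(time[event == 1])
  for (tk in ut) {
    risk <- which(time >= tk)
    dead <- which(time == tk & event == 1)
    d <- length(dead)
    S0 <- sum(ex[risk])
    S1 <- drop(crossprod(X[risk, , drop = FALSE], ex[risk]))
    S2 <- crossprod(X[risk, , drop = FALSE] * sqrt(ex[risk]))
    E0 <- sum(ex[dead])
    E1 <- drop(crossprod(X[dead, , drop = FALSE], ex[dead]))
    E2 <- crossprod(X[dead, , drop = FALSE] * sqrt(ex[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      frac <- if (ties == "efron") l / d else 0
      phi0 <- S0 - frac * E0
      phi1 <- S1 - frac * E1
      phi2 <- S2 - frac * E2
      ll <- ll - log(phi0)
      grad <- grad - phi1 / phi0
      hess <- hess - (phi2 / phi0 - tcrossprod(phi1 / phi0))
    }
    grad <- grad + colSums(X[dead, , drop = FALSE])
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

# partial log-likelihood value only (no derivatives); used inside
# step-halving where the full Hessian would be wasted
cox_pl_value <- function(beta, X, time, event, ties) {
  X <- as.matrix(X)
  o <- order(time)
  X <- X[o, , drop = FALSE]; time <- time[o]; event <- event[o]
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  ex <- exp(eta)
  ll <- 0
  for (tk in unique(time[event == 1])) {
    risk <- time >= tk
    dead <- time == tk & event == 1
    d <- sum(dead)
    S0 <- sum(ex[risk]); E0 <- sum(ex[dead])
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    ll <- ll + sum(eta[dead]) - sum(log(S0 - frac * E0))
  }
  ll
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson with step-halving on the partial likelihood
#' (Efron tie correction by default); standard errors from the
#' observed information.  Monotone likelihood (perfect risk
#' separation) is flagged.
#'
#' @inheritParams cox_partial_loglik
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `coef`, `se`, `vcov`, `loglik`, `loglik_null`,
#'   `converged`, `flagged`, `n_events`.
#' @export
fit_cox <- function(X, time, event, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (any(time <= 0)) stopf("time must be positive")
  if (sum(event) < 1) stopf("at least one event required")
  p <- ncol(X)
  beta <- rep(0, p)
  flagged <- FALSE; conv <- FALSE
  pl0 <- cox_partial_loglik(beta, X, time, event, ties)
  ll_null <- pl0$loglik
  pl <- pl0
  for (it in seq_len(max_iter)) {
    if (max(abs(pl$gradient)) < tol) { conv <- TRUE; break }
    step <- tryCatch(solve(-pl$hessian, pl$gradient), error = function(e) NULL)
    if (is.null(step)) { flagged <- TRUE; break }
    sh <- 1
    repeat {
      cand <- beta + sh * step
      llc <- cox_pl_value(cand, X, time, event, ties)
      if (llc >= pl$loglik - 1e-12 || sh < 1e-6) break
      sh <- sh / 2
    }
    beta <- beta + sh * step
    pl <- cox_partial_loglik(beta, X, time, event, ties)
    if (max(abs(beta)) > 15) { flagged <- TRUE; break } # monotone likelihood
  }
  vc <- tryCatch(solve(-pl$hessian), error = function(e) matrix(Inf, p, p))
  se <- sqrt(pmax(diag(as.matrix(vc)), 0))
  if (flagged) se[] <- Inf
  list(coef = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
       vcov = vc, loglik = pl$loglik, loglik_null = ll_null,
       converged = conv, flagged = flagged, n_events = sum(event))
}

#' Conventional adjustment covariates as a design matrix
#'
#' Age, BMI, APOE e4, education, smoking as two dummies (former,
#' current; never = reference), the four medication flags, and
#' baseline MMSE; optionally sex and the ATN indicator.
#'
#' @param pheno phenotype table.
#' @param include_sex add the matching factor (for unconditional
#'   sensitivity models and Cox models).
#' @param include_atn add the baseline biomarker-positivity indicator.
#' @return numeric matrix, one row per sample.
#' @export
build_covariates <- function(pheno, include_sex = FALSE, include_atn = FALSE) {
  M <- cbind(age = pheno$age, bmi = pheno$bmi, apoe4 = pheno$apoe4,
             education = pheno$education,
             smoke_former = as.numeric(pheno$smoking == "former"),
             smoke_current = as.numeric(pheno$smoking == "current"),
             med_antidep_anxio = pheno$med_antidep_anxio,
             med_antihtn = pheno$med_antihtn,
             med_statin = pheno$med_statin,
             med_other_lipid = pheno$med_other_lipid,
             mmse = pheno$mmse)
  if (include_sex) M <- cbind(M, sex = pheno$sex)
  if (include_atn) M <- cbind(M, atn = pheno$atn_case)
  M
}

#' Per-feature univariate association screen
#'
#' One model per feature: the feature's standardized expression plus
#' (optionally) the conventional adjustment covariates, fitted as
#' conditional logistic regression of case status (matched pairs), as
#' Cox regression of conversion (additionally adjusted for baseline
#' biomarker positivity), or as the unconditional-logistic
#' sensitivity analysis additionally adjusted for sex.  Estimates are
#' log-OR / log-HR per 1 SD of expression; p-values are BH-adjusted
#' across the feature family, with flagged fits carried as `NA`.
#'
#' @param expr an [snc_expr()] (standardized).
#' @param pheno phenotype table.
#' @param model `"clogit"`, `"cox"`, or `"logistic_sensitivity"`.
#' @param adjusted include the conventional covariates.
#' @return data frame of per-feature association results.
#' @export
run_univariate_screen <- function(expr, pheno,
                                  model = c("clogit", "cox", "logistic_sensitivity"),
                                  adjusted = TRUE) {
  model <- match.arg(model)
  stopifnot(identical(colnames(expr$values), pheno$sample_id))
  Z <- build_covariates(pheno)
  feats <- rownames(expr$values)
  est <- se <- pv <- rep(NA_real_, length(feats))
  flag <- logical(length(feats))
  for (i in seq_along(feats)) {
    x <- expr$values[i, ]
    fit <- tryCatch({
      if (model == "clogit") {
        Xm <- if (adjusted) cbind(feature = x, Z) else cbind(feature = x)
        fit_conditional_logistic(Xm, pheno$pair_id, pheno$atn_case,
                                 verify_equivalence = FALSE)
      } else if (model == "cox") {
        Xm <- if (adjusted)
          cbind(feature = x, build_covariates(pheno, include_sex = TRUE,
                                              include_atn = TRUE))
        else cbind(feature = x)
        fit_cox(Xm, pheno$followup_years, pheno$ad_event)
      } else {
        Xm <- if (adjusted)
          cbind(feature = x, build_covariates(pheno, include_sex = TRUE))
        else cbind(feature = x, sex = pheno$sex)
        g <- stats::glm.fit(cbind(1, Xm), pheno$atn_case,
                            family = stats::binomial())
        sm <- tryCatch(solve(crossprod(sqrt(g$weights) * cbind(1, Xm))),
                       error = function(e) NULL)
        list(coef = g$coefficients[2], flagged = is.null(sm) || !g$converged,
             se = if (is.null(sm)) Inf else sqrt(sm[2, 2]))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) { flag[i] <- TRUE; next }
    est[i] <- fit$coef[1]
    se[i] <- fit$se[1]
    flag[i] <- isTRUE(fit$flagged)
  }
  pv <- ifelse(flag | !is.finite(se), NA, 2 * pnorm(-abs(est / se)))
  tag <- switch(model,
                clogit = if (adjusted) "adjusted" else "unadjusted",
                cox = if (adjusted) "adjusted_plus_atn" else "unadjusted",
                logistic_sensitivity = "sensitivity_unconditional")
  data.frame(feature_id = feats, estimate = est, se = se,
             or_hr = exp(est),
             ci95_low = exp(est - qnorm(0.975) * se),
             ci95_high = exp(est + qnorm(0.975) * se),
             p = pv, padj = bh_adjust(pv),
             flagged = flag, model_tag = tag,
             stringsAsFactors = FALSE)
}
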