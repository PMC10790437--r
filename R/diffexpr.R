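#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-feature dispersion phi in the mean-dispersion parameterization
#' `Var = mu + phi * mu^2`, estimated on normalized counts as
#' `max(0, (s^2 - mean) / mean^2)` and optionally shrunk halfway (in
#' log space) towards a lowess trend of dispersion versus mean.
#'
#' @param counts an [snc_counts()] object or numeric matrix.
#' @param size_factors per-sample factors; computed when `NULL`.
#' @param shrink shrink towards the mean-dispersion trend.
#' @return named non-negative numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors = NULL, shrink = FALSE) {
  m <- if (inherits(counts, "snc_counts")) counts$counts else as.matrix(counts)
  sf <- size_factors %||% size_factors_median_of_ratios(counts)
  q <- sweep(m, 2, sf, `/`)
  mu <- rowMeans(q, na.rm = TRUE)
  s2 <- apply(q, 1, var, na.rm = TRUE)
  if (any(s2 == 0, na.rm = TRUE))
    warnf("%d constant feature(s): dispersion set to 0", sum(s2 == 0, na.rm = TRUE))
  phi <- pmax(0, (s2 - mu) / mu^2)
  phi[!is.finite(phi)] <- 0
  if (shrink && length(phi) >= 10) {
    lm_ <- log(mu + 1e-8); lp <- log(phi + 1e-8)
    tr <- stats::lowess(lm_, lp, f = 0.5)
    trend <- stats::approx(tr$x, tr$y, xout = lm_, rule = 2)$y
    phi <- pmax(0, exp((lp + trend) / 2) - 1e-8)
  }
  setNames(phi, rownames(m))
}

# NB GLM with log link, fixed dispersion, design intercept + group,
# offset log size factors; Fisher scoring.  Returns NA on
# non-convergence or degenerate input.
nb_glm_wald <- function(y, x, offset, phi, max_iter = 50, tol = 1e-8) {
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]; offset <- offset[ok]
  if (length(unique(x)) < 2 || sum(y) == 0)
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  X <- cbind(1, x)
  beta <- c(log(mean(y / exp(offset)) + 1e-8), 0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + phi * mu)
    z <- eta - offset + (y - mu) / mu
    fit <- tryCatch(lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients)))
      return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(delta)) < tol) { conv <- TRUE; break }
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + phi * mu)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  list(beta = beta[2], intercept = beta[1], se = sqrt(vc[2, 2]),
       converged = conv, base_mean = mean(y / exp(offset)))
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-feature NB generalized linear model with log link, design
#' `~ group`, and log size factors as offsets.  The Wald statistic
#' `beta / SE(beta)` is referred to the standard normal (two-sided).
#' Non-converged fits are reported with `NA` p-values and excluded
#' from the Benjamini-Hochberg family (the exclusion count is recorded
#' in the `n_excluded` attribute).
#'
#' @param counts an [snc_counts()] object.
#' @param group binary group labels (0/1) per sample.
#' @param size_factors per-sample factors; computed when `NULL`.
#' @param dispersion per-feature dispersions; estimated when `NULL`.
#' @return data frame with `feature_id`, `baseMean`,
#'   `log2FoldChange`, `se`, `stat`, `pvalue`, `padj`, `direction`.
#' @export
nb_wald_test <- function(counts, group, size_factors = NULL, dispersion = NULL) {
  stopifnot(inherits(counts, "snc_counts"))
  m <- counts$counts
  group <- as.numeric(group)
  if (length(group) != ncol(m)) stopf("group length mismatch")
  if (length(unique(group)) != 2) stopf("exactly two groups required")
  if (min(table(group)) < 2) stopf("each group needs >= 2 samples")
  sf <- size_factors %||% size_factors_median_of_ratios(counts)
  phi <- dispersion %||% estimate_dispersion(counts, sf)
  offs <- log(sf)
  res <- lapply(seq_len(nrow(m)), function(g)
    nb_glm_wald(m[g, ], group, offs, phi[g]))
  beta <- vapply(res, `[[`, numeric(1), "beta")
  se <- vapply(res, `[[`, numeric(1), "se")
  stat <- beta / se
  p <- 2 * pnorm(-abs(stat))
  out <- data.frame(
    feature_id = rownames(m),
    baseMean = vapply(res, function(r) r$base_mean %||% NA_real_, numeric(1)),
    log2FoldChange = beta / log(2),
    se = se / log(2),
    stat = stat,
    pvalue = p,
    padj = bh_adjust(p),
    direction = ifelse(is.na(beta), NA, ifelse(beta >= 0, "up", "down")),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(is.na(p))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min over j >= i of (m / j) * p_(j)`, capped at 1, with
#' the input order restored.  `NA` p-values are excluded from the
#' family size `m` and returned as `NA`.
#'
#' @param p numeric vector of p-values in (0, 1] (NA allowed).
#' @return vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  obs <- which(!is.na(p))
  if (!length(obs)) return(out)
  pv <- p[obs]
  if (any(pv < 0 | pv > 1)) stopf("p-values must be in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[obs[o]] <- adj
  out
}

#' Differential-expression screen on a cohort
#'
#' Convenience wrapper: size factors, dispersions and the NB Wald test
#' for a phenotype contrast (`atn_case` or `ad_event`).
#'
#' @param counts an [snc_counts()] object.
#' @param pheno phenotype table (see [validate_pheno()]).
#' @param contrast phenotype column holding the binary contrast.
#' @return the [nb_wald_test()] result table.
#' @export
run_de <- function(counts, pheno, contrast = c("atn_case", "ad_event")) {
  contrast <- match.arg(contrast)
  stopifnot(identical(colnames(counts$counts), pheno$sample_id))
  nb_wald_test(counts, pheno[[contrast]])
}
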