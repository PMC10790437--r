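#' Filter features with low total read counts
#'
#' Retains exactly the features whose total read count across samples
#' is at least `min_total_reads` (i.e. excludes transcripts with fewer
#' than `min_total_reads` total reads), preserving feature order.
#' Missing cells do not contribute to the total.
#'
#' @param counts an [snc_counts()] object.
#' @param min_total_reads minimum row sum required to keep a feature.
#' @return a filtered [snc_counts()].
#' @export
filter_low_expression <- function(counts, min_total_reads = 1000) {
  stopifnot(inherits(counts, "snc_counts"))
  keep <- rowSums(counts$counts, na.rm = TRUE) >= min_total_reads
  if (!any(keep))
    stopf("no feature has %d or more total reads", min_total_reads)
  remap_cells <- function(cells) {
    if (is.null(cells)) return(NULL)
    newrow <- cumsum(keep)
    sel <- keep[cells[, 1]]
    cbind(newrow[cells[sel, 1]], cells[sel, 2, drop = TRUE])
  }
  out <- snc_counts(counts$counts[keep, , drop = FALSE],
                    counts$feature_class[keep],
                    missing_cells = remap_cells(counts$missing_cells),
                    outlier_cells = remap_cells(counts$outlier_cells))
  attr(out, "artifact_values") <- attr(counts, "artifact_values")
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for sequencing depth and RNA
#' composition: for each sample the median, across reference features,
#' of the ratio of the sample's count to the feature's geometric mean.
#' Reference features are those with no zero (and no missing) count;
#' when none exists, geometric means are computed over positive counts
#' only ("poscounts" fallback) with a warning.
#'
#' @param counts an [snc_counts()] object or a numeric matrix
#'   (features x samples).
#' @return named vector of positive per-sample size factors (not
#'   rescaled further).
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "snc_counts")) counts$counts else as.matrix(counts)
  ref <- rowSums(m > 0, na.rm = TRUE) == ncol(m) & !apply(is.na(m), 1, any)
  if (any(ref)) {
    lg <- log(m[ref, , drop = FALSE])
    geo <- exp(rowMeans(lg))
    ratios <- m[ref, , drop = FALSE] / geo
    sf <- apply(ratios, 2, median)
  } else {
    warnf("no feature with all-positive counts; using poscounts-style geometric means")
    lg <- suppressWarnings(log(m))
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ok <- is.finite(geo) & geo > 0
    if (!any(ok)) stopf("cannot compute size factors: no positive counts")
    ratios <- m[ok, , drop = FALSE] / geo[ok]
    ratios[m[ok, , drop = FALSE] == 0] <- NA
    sf <- apply(ratios, 2, median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0))
    stopf("non-positive size factor for sample(s): %s",
          paste(colnames(m)[!is.finite(sf) | sf <= 0], collapse = ", "))
  setNames(sf, colnames(m))
}

#' Normalize counts and standardize per feature
#'
#' Divides counts by per-sample size factors, applies
#' `log2(x + pseudo_count)`, and (by default) z-standardizes each
#' feature so effect sizes are comparable across sncRNAs.  Missing
#' cells stay missing and are recorded in the mask.
#'
#' @param counts an [snc_counts()] object.
#' @param size_factors per-sample positive factors; computed by
#'   [size_factors_median_of_ratios()] when `NULL`.
#' @param pseudo_count added before the log to avoid `log(0)`.
#' @param standardize z-standardize each feature.
#' @return an [snc_expr()].
#' @export
normalize_and_standardize <- function(counts, size_factors = NULL,
                                      pseudo_count = 0.5, standardize = TRUE) {
  stopifnot(inherits(counts, "snc_counts"))
  sf <- size_factors %||% size_factors_median_of_ratios(counts)
  if (any(sf <= 0)) stopf("size factors must be positive")
  v <- log2(sweep(counts$counts, 2, sf, `/`) + pseudo_count)
  steps <- c(sprintf("normalize(median_of_ratios, pseudo=%g)", pseudo_count))
  if (standardize) {
    v <- row_standardize(v)
    steps <- c(steps, "standardize(z)")
  }
  snc_expr(v, mask = is.na(v), size_factors = sf, transform_log = steps)
}

#' Mask abnormal expression values by per-feature z-score
#'
#' Cells whose per-feature z-score exceeds `z_threshold` in absolute
#' value are added to the mask (treated as missing).  z is computed
#' from each feature's mean and SD over currently unmasked cells.  The
#' reference statistics are recorded on the object at the first call
#' so repeated masking with the same threshold is idempotent.
#' Constant features are skipped with a warning (z undefined).
#'
#' @param expr an [snc_expr()].
#' @param z_threshold absolute z-score beyond which a cell is masked.
#' @return the [snc_expr()] with an enlarged mask.
#' @export
mask_outliers <- function(expr, z_threshold = 3.0) {
  stopifnot(inherits(expr, "snc_expr"))
  v <- expr$values
  v[expr$mask] <- NA
  ref <- expr$outlier_ref
  if (is.null(ref)) {
    mu <- rowMeans(v, na.rm = TRUE)
    s <- apply(v, 1, sd, na.rm = TRUE)
    ref <- list(mean = mu, sd = s)
  }
  const <- !is.finite(ref$sd) | ref$sd < .Machine$double.eps * 1e3
  if (any(const))
    warnf("%d constant feature(s): no outlier masking applied (SD = 0)", sum(const))
  z <- (v - ref$mean) / ifelse(const, Inf, ref$sd)
  new_mask <- expr$mask | (!is.na(z) & abs(z) > z_threshold)
  out_v <- expr$values
  out_v[new_mask] <- NA
  out <- snc_expr(out_v, mask = new_mask, size_factors = expr$size_factors,
                  transform_log = c(expr$transform_log,
                                    sprintf("mask_outliers(z=%g)", z_threshold)))
  out$outlier_ref <- ref
  out
}

#' Impute masked expression values
#'
#' Replaces masked cells with imputed values; unmasked cells are never
#' changed.  `iterative_forest` (the default, mirroring missForest)
#' performs round-robin per-feature regression with randomized tree
#' ensembles on the other features until the imputed values change by
#' less than `tol` (relative) or `max_sweeps` sweeps.  `knn` averages
#' the k nearest features (Euclidean distance on shared observed
#' samples).  `feature_median` substitutes the feature's median of
#' observed cells (fast deterministic baseline).
#'
#' @param expr an [snc_expr()].
#' @param method imputation method.
#' @param seed integer seed for the tree ensembles.
#' @param k neighbours for `knn`.
#' @param ntree trees per ensemble for `iterative_forest`.
#' @param max_sweeps maximum round-robin sweeps.
#' @param tol relative-change convergence tolerance.
#' @return the [snc_expr()] with masked cells filled in (the mask
#'   itself is preserved as provenance).
#' @export
impute_missing <- function(expr,
                           method = c("iterative_forest", "knn", "feature_median"),
                           seed = 1, k = 10, ntree = 25,
                           max_sweeps = 10, tol = 1e-3) {
  stopifnot(inherits(expr, "snc_expr"))
  method <- match.arg(method)
  v <- expr$values
  v[expr$mask] <- NA
  all_miss <- rowSums(!is.na(v)) == 0
  if (any(all_miss))
    stopf("feature(s) entirely missing: %s",
          paste(rownames(v)[all_miss], collapse = ", "))
  if (!any(is.na(v))) {
    out <- expr
    out$transform_log <- c(expr$transform_log, sprintf("impute(%s)", method))
    return(out)
  }

  med <- apply(v, 1, median, na.rm = TRUE)
  filled <- v
  for (g in which(rowSums(is.na(v)) > 0))
    filled[g, is.na(v[g, ])] <- med[g]

  if (method == "knn") {
    targets <- which(rowSums(is.na(v)) > 0)
    for (g in targets) {
      others <- setdiff(seq_len(nrow(v)), g)
      obs <- !is.na(v[g, ])
      d2 <- rowSums((filled[others, obs, drop = FALSE] -
                       matrix(v[g, obs], length(others), sum(obs), byrow = TRUE))^2)
      nb <- others[order(d2)][seq_len(min(k, length(others)))]
      miss <- which(is.na(v[g, ]))
      filled[g, miss] <- colMeans(filled[nb, miss, drop = FALSE])
    }
  } else if (method == "iterative_forest") {
    targets <- which(rowSums(is.na(v)) > 0)
    targets <- targets[order(rowSums(is.na(v))[targets])] # fewest missing first
    prev <- filled
    for (sweep_i in seq_len(max_sweeps)) {
      for (ti in seq_along(targets)) {
        g <- targets[ti]
        obs <- which(!is.na(v[g, ]))
        miss <- which(is.na(v[g, ]))
        Xall <- t(filled[-g, , drop = FALSE])
        pred <- .ert_regress(Xall[obs, , drop = FALSE], v[g, obs],
                             Xall[miss, , drop = FALSE],
                             ntree = as.integer(ntree),
                             mtry = 0L, min_node = 5L, max_depth = 8L,
                             seed = child_seed(seed, g)) # stable across sweeps
        # so the round-robin is a deterministic fixed-point iteration
        filled[g, miss] <- pred
      }
      idx <- is.na(v)
      num <- sum((filled[idx] - prev[idx])^2)
      den <- sum(filled[idx]^2) + 1e-12
      if (sqrt(num / den) < tol) break
      prev <- filled
    }
  }

  out <- snc_expr(filled, mask = expr$mask, size_factors = expr$size_factors,
                  transform_log = c(expr$transform_log, sprintf("impute(%s)", method)))
  out$outlier_ref <- expr$outlier_ref
  out
}

#' Re-standardize an expression matrix per feature
#'
#' @param expr an [snc_expr()].
#' @return the [snc_expr()] with each feature at mean 0, SD 1.
#' @export
standardize_expr <- function(expr) {
  stopifnot(inherits(expr, "snc_expr"))
  out <- snc_expr(row_standardize(expr$values), mask = expr$mask,
                  size_factors = expr$size_factors,
                  transform_log = c(expr$transform_log, "standardize(z)"))
  out$outlier_ref <- expr$outlier_ref
  out
}

#' Full preprocessing chain
#'
#' Low-count filtering, median-of-ratios normalization with log2 and
#' per-feature standardization, z-score outlier masking, imputation of
#' masked cells, and final re-standardization — in the stated order
#' (outlier exclusion before imputation).
#'
#' @param counts an [snc_counts()] object.
#' @param min_total_reads low-count filter threshold.
#' @param z_threshold outlier masking threshold.
#' @param impute_method passed to [impute_missing()].
#' @param pseudo_count passed to [normalize_and_standardize()].
#' @param seed seed for the imputer.
#' @return a standardized [snc_expr()].
#' @export
preprocess_counts <- function(counts, min_total_reads = 1000,
                              z_threshold = 3.0,
                              impute_method = "iterative_forest",
                              pseudo_count = 0.5, seed = 1) {
  kept <- filter_low_expression(counts, min_total_reads)
  expr <- normalize_and_standardize(kept, pseudo_count = pseudo_count)
  expr <- mask_outliers(expr, z_threshold)
  expr <- impute_missing(expr, method = impute_method, seed = seed)
  standardize_expr(expr)
}
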