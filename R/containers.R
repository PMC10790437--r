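#' Raw sncRNA count matrix
#'
#' Container for a features x samples matrix of non-negative integer
#' read counts with per-feature class annotations.  Cells may be `NA`
#' when upstream processing flagged them missing; the positions of
#' injected missing cells and outlier cells (if any) are carried along
#' as two-column index matrices.
#'
#' @param counts features x samples numeric matrix, non-negative, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param feature_class character vector, one of `"miRNA"`, `"piRNA"`,
#'   `"tRNA"`, `"snoRNA"`, `"rRNA"`, `"other"` per feature.
#' @param missing_cells,outlier_cells optional two-column integer
#'   matrices (row, col) recording injected artifacts.
#' @return an object of class `snc_counts`.
#' @export
snc_counts <- function(counts, feature_class = NULL,
                       missing_cells = NULL, outlier_cells = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("feat_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (any(counts < 0, na.rm = TRUE)) stopf("negative counts are not allowed")
  if (is.null(feature_class))
    feature_class <- rep("other", nrow(counts))
  feature_class <- as.character(feature_class)
  if (length(feature_class) != nrow(counts))
    stopf("feature_class length (%d) != number of features (%d)",
          length(feature_class), nrow(counts))
  allowed <- c("miRNA", "piRNA", "tRNA", "snoRNA", "rRNA", "other")
  if (!all(feature_class %in% allowed))
    stopf("feature_class must be one of: %s", paste(allowed, collapse = ", "))
  structure(list(counts = counts,
                 feature_class = setNames(feature_class, rownames(counts)),
                 missing_cells = missing_cells,
                 outlier_cells = outlier_cells),
            class = "snc_counts")
}

#' @export
print.snc_counts <- function(x, ...) {
  cat(sprintf("<snc_counts> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$feature_class)),
                                  table(x$feature_class)), collapse = " "), "\n")
  nmiss <- sum(is.na(x$counts))
  if (nmiss > 0) cat(sprintf("  %d missing cells\n", nmiss))
  invisible(x)
}

#' @export
dim.snc_counts <- function(x) dim(x$counts)

# required phenotype columns and their checks
pheno_columns <- function() {
  c("sample_id", "pair_id", "sex", "atn_case", "a_pos", "t_pos", "n_pos",
    "age", "bmi", "apoe4", "education", "smoking",
    "med_antidep_anxio", "med_antihtn", "med_statin", "med_other_lipid",
    "mmse", "followup_years", "ad_event")
}

#' Validate a phenotype table
#'
#' Checks the per-sample phenotype data frame against the matched
#' nested case-control design: every pair id appears exactly twice,
#' pairs are concordant on sex (the matching factor) and discordant on
#' case status, ATN component calls are consistent with the A+(T|N)+ /
#' A-T-N- contrast, and follow-up times are positive.
#'
#' @param pheno data frame with the columns of [pheno_columns()].
#' @return `pheno`, invisibly, after validation.
#' @export
validate_pheno <- function(pheno) {
  miss <- setdiff(pheno_columns(), names(pheno))
  if (length(miss)) stopf("phenotype table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(pheno$sample_id)) stopf("duplicate sample ids")
  tab <- table(pheno$pair_id)
  if (any(tab != 2L)) stopf("each pair_id must appear exactly twice")
  sp <- split(pheno, pheno$pair_id)
  ok_sex <- vapply(sp, function(d) d$sex[1] == d$sex[2], logical(1))
  if (!all(ok_sex)) stopf("pairs must be sex-concordant")
  ok_cc <- vapply(sp, function(d) setequal(d$atn_case, c(0L, 1L)), logical(1))
  if (!all(ok_cc)) stopf("pairs must be case-control discordant on atn_case")
  if (any(pheno$followup_years <= 0)) stopf("followup_years must be > 0")
  cases <- pheno$atn_case == 1
  if (any(pheno$a_pos[cases] != 1 | (pheno$t_pos[cases] == 0 & pheno$n_pos[cases] == 0)))
    stopf("atn_case=1 requires a_pos=1 and t_pos or n_pos = 1")
  if (any(pheno$a_pos[!cases] != 0 | pheno$t_pos[!cases] != 0 | pheno$n_pos[!cases] != 0))
    stopf("atn_case=0 requires a_pos=t_pos=n_pos=0")
  if (!all(pheno$smoking %in% c("never", "former", "current")))
    stopf("smoking must be never/former/current")
  invisible(pheno)
}

#' Normalized expression matrix
#'
#' Features x samples real-valued matrix after normalization and
#' (optionally) per-feature z-standardization, together with the mask
#' of cells that were missing or excluded as outliers, the per-sample
#' size factors, and a record of the transformation steps applied.
#'
#' @param values features x samples numeric matrix.
#' @param mask logical matrix of the same shape; `TRUE` marks cells
#'   that were originally missing or were masked as outliers.
#' @param size_factors per-sample positive scaling factors.
#' @param transform_log character vector of applied steps.
#' @return an object of class `snc_expr`.
#' @export
snc_expr <- function(values, mask = NULL, size_factors = NULL,
                     transform_log = character()) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(mask), dim(values))) stopf("mask shape mismatch")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(values))
  if (any(size_factors <= 0)) stopf("size factors must be positive")
  structure(list(values = values, mask = mask,
                 size_factors = setNames(as.numeric(size_factors), colnames(values)),
                 transform_log = transform_log),
            class = "snc_expr")
}

#' @export
print.snc_expr <- function(x, ...) {
  cat(sprintf("<snc_expr> %d features x %d samples; %d masked cells\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  if (length(x$transform_log))
    cat("  steps:", paste(x$transform_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.snc_expr <- function(x) dim(x$values)
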