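#' Write / read the count matrix as TSV
#'
#' Features in rows; the first two columns are `feature_id` and
#' `feature_class`, followed by one column per sample.
#'
#' @param counts an [snc_counts()].
#' @param file path.
#' @return `file`, invisibly (writer); an [snc_counts()] (reader).
#' @export
write_counts_tsv <- function(counts, file) {
  stopifnot(inherits(counts, "snc_counts"))
  df <- data.frame(feature_id = rownames(counts$counts),
                   feature_class = unname(counts$feature_class),
                   counts$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$feature_id
  snc_counts(m, df$feature_class)
}

#' Write / read the phenotype table as CSV
#'
#' Uses exactly the canonical column set (see [pheno_columns()]).
#'
#' @param pheno phenotype data frame.
#' @param file path.
#' @return `file`, invisibly (writer); validated data frame (reader).
#' @export
write_pheno_csv <- function(pheno, file) {
  validate_pheno(pheno)
  write.csv(pheno[, pheno_columns()], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(file) {
  pheno <- read.csv(file, stringsAsFactors = FALSE)
  validate_pheno(pheno)
  pheno
}

#' Write an expression matrix as TSV plus a JSON sidecar
#'
#' The TSV holds the values (features x samples); the sidecar records
#' size factors, masked-cell coordinates and the transform log.
#'
#' @param expr an [snc_expr()].
#' @param file TSV path; the sidecar is `paste0(file, ".json")`.
#' @return `file`, invisibly.
#' @export
write_expr_tsv <- function(expr, file) {
  stopifnot(inherits(expr, "snc_expr"))
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  mask_idx <- which(expr$mask, arr.ind = TRUE)
  jsonlite::write_json(
    list(size_factors = as.list(expr$size_factors),
         mask_cells = if (nrow(mask_idx)) unname(apply(mask_idx, 1, as.list)) else list(),
         transform_log = expr$transform_log),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Serialize a signature as JSON and TSV
#'
#' The TSV lists the selected features with class, occurrence count,
#' mean coefficient and its percentile CI; the JSON additionally
#' carries the hyperparameters, all occurrence counts and the
#' performance block.
#'
#' @param signature an `snc_signature`.
#' @param feature_class optional named class vector for the TSV.
#' @param file base path without extension; writes `<file>.json` and
#'   `<file>.tsv`.
#' @return `file`, invisibly.
#' @export
write_signature <- function(signature, file, feature_class = NULL) {
  stopifnot(inherits(signature, "snc_signature"))
  sel <- signature$selected_features
  tsv <- data.frame(
    feature_id = sel,
    class = if (is.null(feature_class)) NA else unname(feature_class[sel]),
    occurrences = unname(signature$occurrences[sel]),
    mean_coef = unname(signature$mean_coef),
    ci_low = if (length(sel)) signature$coef_ci95[, "ci_low"] else numeric(0),
    ci_high = if (length(sel)) signature$coef_ci95[, "ci_high"] else numeric(0),
    stringsAsFactors = FALSE)
  write.table(tsv, paste0(file, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(endpoint = signature$endpoint,
         alpha_star = signature$alpha_star,
         lambda_star = signature$lambda_star,
         occurrence_threshold = signature$config$occurrence_threshold,
         stability_iters = signature$config$stability_iters,
         occurrences = as.list(signature$occurrences),
         selected = tsv,
         performance = signature$performance),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
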