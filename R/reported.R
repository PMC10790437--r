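#' Recompute descriptive percentages from reported group counts
#'
#' Reads the bundled table of published per-group counts (sample
#' sizes, AD-conversion counts and A/T/N biomarker-positive counts of
#' the cohort the generator emulates) and recomputes the descriptive
#' percentages from the raw counts.
#'
#' @param file optional path to a counts CSV with columns `group`,
#'   `n`, `converted`, `a_pos`, `t_pos`, `n_pos`; defaults to the
#'   table bundled with the package.
#' @return data frame with per-group percentages (one decimal place
#'   is how such tables are printed; values are returned unrounded).
#' @export
reported_cohort_percentages <- function(file = NULL) {
  file <- file %||% system.file("extdata", "reported_group_counts.csv",
                                package = "sncsig", mustWork = TRUE)
  df <- read.csv(file, stringsAsFactors = FALSE)
  data.frame(group = df$group,
             n = df$n,
             pct_converted = 100 * df$converted / df$n,
             pct_a_pos = 100 * df$a_pos / df$n,
             pct_t_pos = 100 * df$t_pos / df$n,
             pct_n_pos = 100 * df$n_pos / df$n,
             stringsAsFactors = FALSE)
}
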