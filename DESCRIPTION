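Package: sncsig
Title: Plasma Small Non-Coding RNA Signatures for ATN Status and
    Alzheimer's Disease Conversion
Version: 0.1.0
Authors@R:
    person("ACE", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering plasma small non-coding
    RNA (sncRNA) signatures of CSF biomarker (ATN) positivity and of
    conversion from mild cognitive impairment to Alzheimer's disease in
    1:1 sex-matched nested case-control cohorts.  Implements low-count
    filtering, z-score outlier masking, tree-ensemble imputation,
    median-of-ratios normalization, negative-binomial differential
    expression with Benjamini-Hochberg correction, conditional logistic
    and Cox proportional-hazards screening, elastic-net penalized
    conditional-logistic and Cox fitting with cross-validated
    hyperparameter search, 100-iteration stability selection with an
    occurrence threshold, weighted-score construction, and nested Cox
    model comparison via likelihood-ratio tests and Harrell's
    C-statistic with bootstrap confidence intervals.  A synthetic cohort
    generator with planted effects makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    glmnet,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
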