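Package: rccpsa
Title: Proportional Molecular Subtyping and Risk Prediction for Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous, reference-based molecular subtyping of renal cell
    carcinoma (RCC) expression profiles. Bulk tumor transcriptomes are
    deconvolved against a signature matrix of median linear expression per
    subtype (clear cell, papillary, chromophobe) using Huber robust
    regression; regression weights are normalized into subtype proportions
    (c, p, h) summing to 100%, with a permutation goodness-of-fit P-value
    and a heterogeneity call. Tools are included to derive subtype-specific
    signature genes from a labeled training cohort, to map the ccRCC
    proportion to a cubic-polynomial Cox prognostic index, to discover
    survival risk-group cutpoints by significance-tested recursive log-rank
    splitting, and to simulate synthetic cohorts with known subtype mixtures
    and survival for testing and calibration.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    survival,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
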