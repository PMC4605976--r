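Package: plsdafuse
Title: Bootstrap PLS-DA Biomarker Selection for Fused Metabolomic Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discriminant biomarker workflow for two-group metabolomic
    cohorts profiled in several biofluids. Concentration blocks (e.g. serum,
    urine, exhaled breath condensate) are fused by low-level concatenation
    and modelled with NIPALS PLS-DA. Model/test partitions are built with
    the Kennard-Stone algorithm applied per group so the model set is
    balanced; variables are selected by bootstrap-averaged VIP scores
    (iterated rounds) or by the selectivity ratio after target projection,
    with a discriminating-variable (DIVA/MCCR) aid for the SR cut-off.
    Performance is summarised as bootstrap mean AUC with its standard
    error plus test-set AUC, sensitivity, specificity and efficiency.
    Includes a synthetic cohort generator with planted effects and
    spectrum fixtures for probabilistic quotient normalization and
    equal-width binning, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
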