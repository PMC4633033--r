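Package: bmiconn
Title: Multimodal Brain Connectivity Networks and BMI Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject structural (fiber-density) and functional
    (Fisher-z correlation) brain connectivity networks, finds edges that
    separate healthy-weight from non-healthy-weight groups by max-statistic
    permutation testing with family-wise error control, couples significant
    structural edges to region-level mean functional connectivity, and
    predicts body mass index from the resulting multimodal feature set with
    partial least-squares regression under nested leave-one-subject-out
    cross-validation. Includes a synthetic cohort generator with planted
    group effects, controllable structure-function coupling and a linear
    BMI link, so the whole workflow is testable without access-restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
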