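Package: survcutpoint
Title: Optimal Cut-Point Selection and Cross-Validated Inference for
    Survival Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Dichotomizes a continuous biomarker against censored survival
    outcomes by scanning candidate thresholds for the maximal log-rank
    chi-square, and tests the data-derived cut-point honestly with a
    two-fold cross-validated stratified log-rank procedure that corrects
    the multiple-cutoff selection bias.  Includes Kaplan-Meier estimation,
    (stratified) log-rank tests, Cox proportional-hazards reporting with
    clinical covariate encodings, baseline-table group comparisons, and a
    simulator of remission cohorts with a threshold hazard effect of a
    platelet-recovery marker, so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
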