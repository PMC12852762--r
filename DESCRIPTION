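Package: macetrial
Title: Target Trial Emulation of Antipsychotic Strategies and Cardiovascular Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for emulating a multi-arm target
    trial of antipsychotic initiation strategies (aripiprazole, olanzapine,
    quetiapine, risperidone) on five-year risk of major adverse cardiovascular
    events, using linked primary-care, hospital-admission, and
    death-registration style tables. Includes a synthetic linked-EHR cohort
    generator with known ground truth; trial-emulation cohort construction
    (eligibility, index date, composite MACE outcomes, per-protocol censoring);
    multiple imputation by chained equations; multinomial propensity models
    with generalised overlap and inverse-probability-of-treatment weights and
    balance diagnostics; discrete-time pooled logistic hazard models with
    g-formula risk standardisation; inverse-probability-of-censoring weights
    for per-protocol estimands; and multiple-imputation plus stratified
    bootstrap inference with bias-corrected and accelerated confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    boot,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
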