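Package: sccsim
Title: Sufficient-Component-Cause Simulations for Teaching Causal Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative sufficient-component-cause (SCC) models over binary
    variables, an exact enumeration truth oracle, hierarchical individual-level
    data generation, potential-outcome response-type classification, and
    crude, stratified and direct-standardized risk-ratio / risk-difference
    estimation. Ships four canned teaching scenarios (causation, confounding,
    collider/selection bias, effect-measure modification) built around the
    example of low educational attainment and dementia, with a command-line
    runner for repeated-sampling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
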