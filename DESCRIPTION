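Package: phenosel
Title: Phenotypic Selection on Correlated Phenological Traits
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates phenotypic selection on vegetative and reproductive
    phenology from discrete census data. Converts interval-censored field
    observations into continuous leaf-out and first-flowering dates, computes
    seed-predation-corrected fitness, and fits Lande-Arnold selection models
    (total differentials, direct gradients, quadratic and correlational
    selection) with bias-corrected and accelerated (BCa) bootstrap intervals
    implemented from first principles. Includes a synthetic-data generator
    with a known selection surface and census observation layer so the whole
    pipeline can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
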