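Package: arsmr
Title: Two-Sample Mendelian Randomization of Arsenic Metabolism and
    Pulmonary Function
Version: 0.1.0
Authors@R:
    person("Maintainer", "arsmr", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the effect of urinary arsenic metabolism efficiency
    (%iAs, %MMA, %DMA) on asthma and spirometry-based pulmonary traits by
    two-sample Mendelian randomization with a correlated-instrument
    principal-components IVW estimator. Ships a literature instrument of
    three single nucleotide variants near AS3MT and FTCD, a synthetic
    cohort generator with household/sibship/block-group clustering and
    linkage disequilibrium matched to the instrument, spirometry
    lower-limit-of-normal phenotyping, and mixed-model genetic association
    with kinship, household and block-group random effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
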