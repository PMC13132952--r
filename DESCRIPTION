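Package: twinpanel
Title: Genetically Informative Twin Models for Longitudinal Wellbeing and
    Life Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-group full-information maximum-likelihood (FIML)
    estimation of twin structural models on raw data with missingness:
    trivariate Cholesky ACE/AE variance decomposition of a three-wave
    phenotype, a genetically informative random-intercept cross-lagged
    panel model (RI-CLPM) linking wellbeing to life-event clusters, twin
    and phenotypic correlations with event-category screening, a
    synthetic twin-pair data generator with realistic wave-participation
    missingness, and a parameter-recovery simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
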