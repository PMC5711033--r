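Package: mrsteiger
Title: Causal Direction Inference Between Traits from Genetic Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the direction of causation between two quantitative traits
    that share a genetic instrument, using the MR Steiger test (a comparison of
    the instrument's correlations with the two traits via Fisher's z-transform
    and Steiger's test for correlated or independent correlations), in both
    one-sample (individual-level) and two-sample (GWAS summary statistic)
    settings. Provides Wald-ratio and two-stage least squares causal effect
    estimation, a measurement-error sensitivity analysis (attenuation factor,
    the d statistic, and the reliability ratio R obtained by integrating the
    predicted test surface over all admissible measurement-error values), a
    reimplementation of the mediation-based causal inference test (CIT) as a
    comparator, and a simulation framework for evaluating both methods under
    measurement error and genetic confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
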