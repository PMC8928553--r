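Package: aqbd
Title: Analytical Quality by Design Tools for Chromatographic Method
    Development
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the computational stages of an Analytical Quality
    by Design (AQbD) workflow for liquid-chromatography method
    development: linear coding of method parameters, polynomial
    response-surface models with ANOVA diagnostics, A- and G-optimal
    experimental design by Fedorov exchange, Derringer-style desirability
    scoring, Monte-Carlo process-capability (Cpk) robustness mapping of a
    Method Operable Design Region (MODR), and ICH-style validation
    statistics (recovery, RSD, response factors, linearity,
    signal-to-noise).  Ships the fitted critical-method-attribute models
    and validation tables of a UHPLC impurity method for the HIV
    integrase inhibitor cabotegravir, plus a synthetic chromatogram
    generator (exponentially modified Gaussian peak trains) so the whole
    pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
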