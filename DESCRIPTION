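Package: twinpath
Title: Polygenic Score Effects on Academic Adjustment via Random-Intercept
    Panel and Mediation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how polygenic scores for smoking and
    educational attainment relate to academic adjustment across
    adolescence and to educational attainment in adulthood.  Implements a
    twin-family cohort simulator with stable-trait plus autoregressive
    occasion structure, multi-informant composite measures, univariate
    random-intercept panel models estimated by full-information maximum
    likelihood, maximum a posteriori factor scoring of the stable traits,
    a recursive path (mediation) model with direct/indirect effect
    decomposition, family-clustered nonparametric percentile bootstrap
    confidence intervals, and reporting helpers for descriptive and
    attenuation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
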