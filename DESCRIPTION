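Package: aagrowth
Title: Growth-Rate Estimation for Abdominal Aortic Aneurysm Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Five estimators of abdominal aortic aneurysm (AAA) growth rate
    from longitudinal surveillance diameter measurements: the first-last
    chord, unpooled linear regression, an unpooled offset-exponential curve
    d(t) = exp(a (t + b)) + 2 with a linear fallback, and hierarchical
    Bayesian linear and offset-exponential mixed-effects models fitted by
    MCMC. Includes a synthetic surveillance-cohort simulator, the
    preprocessing rules used in clinical surveillance datasets (merging of
    close-together measurements, minimum-measurement filters, endpoint
    censoring, forecast train/target splits), benchmark-rate
    standardisation at the 4.0/4.5 cm diameters, and an evaluation suite
    covering censoring stability, future-diameter forecasting and
    nonparametric risk-factor screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
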