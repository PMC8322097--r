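Package: scampi
Title: Statistical Classification Analysis of Membrane Protein Images
Version: 0.1.0
Authors@R:
    person("SCAMPI", "Maintainers", email = "scampi@example.org", role = c("aut", "cre"))
Description: Pixel-based statistical discrimination of grayscale fluorescence
    microscopy images of membrane proteins. Each image is modelled as a
    spatial-lag (digital PDE) regression fitted by ordinary least squares with
    a White heteroskedasticity-robust covariance; per-image model parameters
    are classified with a two-class Fisher linear discriminant, and class
    membership probabilities are obtained by logistic regression on the
    discriminant projections. Includes baseline image statistics
    (threshold-based spreading area, lognormal signal fits, normality and
    distribution-comparison tests), a seeded synthetic-image simulator for
    end-to-end testing, and a reproducible command-line pipeline with CSV and
    JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
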