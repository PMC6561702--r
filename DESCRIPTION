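Package: cliffwind
Title: Wind-Dependent Landing Success in Cliff-Nesting Seabirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how wind limits the ability of cliff-nesting
    auks (guillemots and razorbills) to land at their breeding ledges.
    Post-processes wind-field output (turbulent kinetic energy, velocity
    perturbation, turbulence intensity, log-profile height adjustment,
    sea-to-cliff scaling), fits binomial mixed-effects models of per-attempt
    landing success with a day-colony random intercept, collapses a fitted
    model to a logistic landing-probability curve, propagates it through a
    log-normal model of instantaneous cliff winds to the geometric
    distribution of attempts needed to land, converts attempt counts to
    energetic costs, and provides circular statistics (mean direction,
    Rayleigh uniformity test) for colony orientations. A synthetic-data
    generator reproduces the statistical structure of the field observations
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
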