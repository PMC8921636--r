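Package: clonopower
Title: Detection Power Calculations for Bulk T-Cell Receptor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical power calculations for detecting a target T-cell
    receptor (TCR) clonotype by bulk TCR sequencing. Models clonotype read
    counts in two steps: Poisson subsampling of T cells from the body into a
    blood sample, and a negative-binomial read-count model with a power-law
    mean-variance relationship (sigma^2 = mu + eta * mu^lambda) describing
    library preparation and sequencing noise. The read model is calibrated by
    maximum likelihood from spike-in clonotypes of known sample frequency.
    Provides detection probabilities under read-count thresholds, minimal
    detectable clonotype frequencies with bootstrap confidence intervals,
    power grids over sample size and sequencing depth, utilities for
    processing MiXCR-style clonotype tables (IMGT junction trimming, spike-in
    matching, false-positive and read-cutoff analysis), and a seeded
    generator of synthetic spike-in experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
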