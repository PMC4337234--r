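Package: changegrid
Title: State-Space-Grid Dispersion and Outcome Analysis for Coded Psychotherapy
    Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pattern destabilization in psychotherapy from
    observational session codings. Converts two-coder ordinal CHANGE ratings
    (0-3) into multimodal pattern strength (0-12) and activation (0-4) scores,
    builds per-patient per-phase 5x5 state-space grids, computes grid
    dispersion, extracts peak emotional processing and baseline/posttreatment
    pattern strengths, and reproduces the outcome layer: paired t-tests with
    Cohen's d, pairwise correlation matrices, hierarchical regressions with
    R-squared-change F tests, inter-rater ICC, and standardized regressions
    reconstructed from a printed correlation matrix. A seeded synthetic-cohort
    generator (two-state flickering Markov chains with ordinal emissions and
    planted outcome coefficients) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    knitr
Config/testthat/edition: 3
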