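Package: monson
Title: Monson's Sphere Analysis of Dental Occlusal Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Monson's sphere -- the hypothetical sphere that the cusp
    tips of a natural dentition approximately touch -- to 26 labelled
    cusp-tip landmarks by algebraic (Kasa) and geometric (orthogonal
    distance) least squares, and runs the surrounding workflow: landmark
    CSV input/output and validation, cusp-tip detection on triangulated
    dental surface meshes (STL), intrarater reliability via two-way
    single-measures intraclass correlation coefficients with exact F-based
    confidence intervals, cohort statistics (descriptive summaries,
    one-sample t-test against the classical four-inch radius, Mann-Whitney
    U between sexes), and a seeded synthetic-dentition generator so every
    stage is testable without real scans. A command-line interface exposes
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
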