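Package: cpscope
Title: Quality Metrics and Acquisition-Setting Experiments for Cell
    Painting Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for grading Cell Painting imaging configurations from
    morphological feature tables: generation and validation of JUMP-MOA
    style 384-well plate maps, a synthetic single-cell feature simulator
    with compound- and mechanism-of-action-level effect structure,
    well-profile construction (mean aggregation, per-plate MAD
    robustization, feature selection, channel-feature dropout), the
    percent-replicating / percent-matching resampling statistics with
    their null distributions, and orchestration of setting-perturbation
    experiments (site subsampling and cell-count curves, channel dropout,
    leaderboard scoring).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
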