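Package: sptkin
Title: Single-Particle Tracking Simulation and Jump-Length Kinetic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of live-cell single-molecule tracking
    experiments for nuclear factors such as DNMT1. Generates ground-truth
    Brownian trajectories and rendered movies for a three-state
    (chromatin-bound, slow-diffusing, fast-diffusing) mixture with
    localization error and an axial detection slice; detects and localizes
    diffraction-limited spots to subpixel precision; links localizations
    into trajectories with gap closing; compiles jump-length histograms and
    fits two- and three-state diffusion models with localization-error and
    defocalization corrections; and aggregates per-cell fits for group
    comparisons, bimodality assessment, and auxiliary quantifications
    (size-scaling regression, molecule counting, fractionation ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    minpack.lm,
    mclust,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
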