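Package: needlehydro
Title: Needle Xylem Anatomy and Theoretical Hydraulic Conductivity of Conifer Needles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drought and canopy-position effects on conifer
    needle anatomy. Computes per-tracheid theoretical hydraulic conductivity from
    lumen diameters with the elliptical-conduit modification of the
    Hagen-Poiseuille law, aggregates tracheid measurements to needle-level
    anatomical and hydraulic traits, fits hierarchical linear mixed-effects
    models with shoot-within-tree random intercepts and likelihood-ratio tests
    for treatment effects, and derives the percent-reduction and fold-difference
    comparison statistics used to summarise sun/shade needle plasticity. Includes
    a calibrated hierarchical synthetic-data generator emulating a
    two-treatment, two-canopy-position sampling design and a geometric
    cross-section surrogate that rasterizes idealised needle sections to
    quantify area-measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
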