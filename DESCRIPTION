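Package: sketchcomm
Title: Analysis of Repeated Drawing-Based Reference Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ad hoc graphical conventions form when
    pairs of people repeatedly communicate about visual objects by drawing.
    Provides communication-efficiency scoring (the balanced integration
    score, a speed-accuracy composite), trajectory analyses of drawing
    similarity in a deep-feature-style embedding space (within-dyad
    convergence, between-dyad divergence, and a label-scrambling
    permutation null), pixel-level diagnosticity scoring of drawings
    against crowdsourced-style annotation masks and heatmaps, generators
    for the pre/repetition/post session design and its yoked and shuffled
    recognition controls, and a seeded synthetic-data generator that
    emulates dyadic convention formation so the full pipeline can be
    exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
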