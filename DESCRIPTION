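Package: amoebaCA
Title: Time-Lapse Activity Quantification and Two-Phase Colonization
    Kinetics for Amoeba Microcosms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies amoeba behavior in time-lapse microscopy of
    microbial microcosms by consecutive-frame differencing with an
    inactive-region-derived threshold, builds cumulative activity (CA)
    curves, and fits a two-phase excystation/colonization model (a
    mono-exponential inoculum phase followed by a logistic colonization
    phase) to extract six behavioral parameters (cIA, cCA, tx, tp, tc,
    tg) with window censoring for non-colonizing conditions. Includes a
    synthetic-microcosm generator (noisy CA curves and rendered image
    stacks with full ground truth), replicate-level summaries, and
    one-way ANOVA with Tukey HSD compact letter displays for condition
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    minpack.lm,
    tiff,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
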