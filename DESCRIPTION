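Package: viewfeat
Title: Low-Level Visual Features of Window Views and Their Links to
    Affect and Impulsive Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies residential window views from photographs by
    fourteen low-level visual features (circular hue statistics,
    saturation and brightness moments, green/blue/sky pixel ratios,
    Canny edge density split into straight and non-straight components,
    gray-level entropy, and box-counting fractal dimension), scores two
    behavioral outcomes (a state negative-affect composite from a 20-item
    anxiety-depression inventory, and delay-discounting indifference
    points with their normalized area under the curve from adaptive
    staircase choice logs), and links features, subjective view ratings,
    and outcomes through Spearman correlation matrices and bidirectional
    AIC-stepwise regression with forced-entry blocks.  Includes a
    synthetic scene-and-cohort generator with exact ground truth so the
    full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jpeg,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
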