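Package: spreadsel
Title: Metaphase Spread Selection by Rule-Based Chromosome Object Classification
Version: 0.1.0
Authors@R: person("Spreadsel", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens Giemsa-stained metaphase spread images for karyotyping
    suitability. Objects are segmented from each spread by histogram
    equalization and Otsu thresholding, rotated to their principal vertical
    orientation, and classified by a rule tree over geometric shape ratios
    into straight individual chromosomes, skewed individual chromosomes,
    touching/overlapping chromosome clusters, and non-chromosome residues.
    Spreads are ranked by their count of individual chromosomes with a
    documented tie-break cascade. Includes Gaussian-intercept threshold
    calibration from labeled feature samples, a synthetic spread generator
    with per-object ground truth for validation, and a command-line driver
    for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
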