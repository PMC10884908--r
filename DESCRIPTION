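Package: sheetscan
Title: Label-Free Cell Counting from Flatbed-Scanner Images with a Pattern Sheet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting adherent cultured cells from consumer
    flatbed-scanner images taken through a perforated "pattern sheet".
    Implements the information volume map (a difference-of-Gaussians
    object-likelihood transform), scan and map quality metrics (brightness,
    deviation, object contrast, cross-entropy against phase-contrast cell
    regions), a rule-based cell detector with density conversion, a
    four-way error taxonomy against nuclear ground truth, pattern-sheet
    visualization-band coverage geometry, a simplified 2-D Monte-Carlo ray
    tracer for the shading mechanism, field-of-view sampling-bias
    simulation, and a seeded synthetic scene generator that provides full
    ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
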