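Package: cladotrace
Title: Cell Lineage Statistics and Cladograms from Annotated Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses plain-text cell-event annotation files from time-lapse
    video-microscopy (cell appearance, division, fusion, death, field exit),
    builds a validated lineage forest, computes single-cell fate statistics
    (mitosis counts and quality, fusion and death tallies, inter-mitosis
    intervals, per-day event ratios, per-cell division counts) and renders
    lineage cladograms as standalone SVG. Includes a seeded stochastic
    branching-process simulator that emits event files with known
    ground-truth tallies for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
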