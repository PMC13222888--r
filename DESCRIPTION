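Package: ldrank
Title: Partial-Order Ranking of Land Degradation Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for county-scale attribution of land degradation drivers
    using partial order theory and the Hasse diagram technique. Provides
    land-cover change accounting (reclassification, class-to-class transition
    matrices, degradation/restoration flagging and annual change rates),
    driver preprocessing (zonal means, inverse-distance-weighted
    interpolation, min-max normalization and directional orientation),
    Hasse diagram construction over areal units (cover relations, level
    assignment, maximal chains, isolated elements, LPOM0 average ranks),
    per-unit dominant-driver-group identification, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
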