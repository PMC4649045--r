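Package: raypar
Title: Quantification of Conifer Ray Parenchyma on Virtual and Real Wood Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying xylem ray parenchyma in conifers. Provides a
    seeded generator of three-dimensional stem-sector models with fusiform
    uniseriate rays, a virtual microtome that cuts finite-thickness,
    possibly misaligned sections in the cross-sectional, tangential and
    radial planes and rasterizes maximum-projection label maps, extraction
    of per-ray outlines and per-ring statistics (percentage of ray surface,
    initiating and disappearing rays, ray dimensions, early/latewood
    splits), bootstrap accuracy analysis of window-based sampling with
    confidence-interval and sample-size planning, and the classical
    statistics used in quantitative wood anatomy (coefficient of variation,
    mean sensitivity, Pearson correlation matrices, paired comparisons and
    allometric regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
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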