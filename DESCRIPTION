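Package: paleodisp
Title: Morphological Disparity Through Time from 2D Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for 2D geometric morphometrics of
    fossil taxa: reads TPS landmark files, sliders definitions and species
    metadata; performs generalized Procrustes analysis with iterative
    semi-landmark sliding under the Procrustes-distance minimisation
    criterion; ordinates shapes by principal component analysis; computes
    group-wise disparity statistics (Procrustes variance with permutation
    pairwise tests, convex-hull and variance-weighted hull areas, sum of
    variances); bins taxa on geological time scales for
    disparity-through-time and range-through richness curves; and supports
    Lagerstaette-effect jackknife re-analyses. Includes a synthetic
    landmark-data generator with known truth for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
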