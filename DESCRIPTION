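Package: clearkin
Title: Clearance Kinetics of Developmental Cell Death and Retinal Mosaic Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring corpse clearance times from snapshot
    measurements of visibly dying cells during developmental cell loss.
    Implements the closed-form death-window model linking a starting cell
    count, a final cell count, a visible-dying fraction and a clearance
    (visibility) time, together with its inference permutations: solving
    for the clearance time, projecting population decline, extrapolating
    cumulative losses, and propagating confidence bands on the dying
    fraction into expected corpse-density bands. Also provides a seeded
    stochastic death-and-clearance simulator with snapshot observation,
    generators for retinal point patterns and label-mask scenes with known
    ground truth, area-weighted stereological estimation of total cell
    number from regional density samples, and spatial quantification
    indices used in retinal glia studies: Voronoi domain regularity,
    lysosome index, network coverage, engulfment classification and
    debris localization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
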