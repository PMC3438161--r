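Package: polargrowth
Title: Division-Site Placement and Asymmetric Polar Growth in Rod-Shaped
    Bacteria from Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of division-site placement and bipolar
    elongation in rod-shaped actinobacteria (mycobacteria, corynebacteria)
    from single-cell time-lapse fluorescence microscopy.  Provides a
    synthetic two-channel movie generator emulating bipolar exponential
    growth with unequal pole rates, a wandering pre-septal fluorescent
    patch that condenses into a stable mid-cell spot, and timer-triggered
    division; segmentation of rod cells with sub-pixel centerline length
    measurement; maximal-intensity-pixel focus detection, classification
    and tracking; cell lineage tracking with division detection; and the
    population statistics of septum placement (normalized positions,
    central-band fractions), per-pole exponential growth-rate estimation,
    growth asymmetry, and length-variability comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
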