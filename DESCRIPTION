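Package: punctakit
Title: Quantification of Punctate Fluorescence, Membrane Binding and
    Endocytosis in TIRF and PLA Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying diffraction-limited fluorescent puncta in
    total internal reflection fluorescence (TIRF) and widefield microscopy:
    prominence-based spot detection in the style of ImageJ's "find maxima",
    cluster density per membrane area, the circle-annulus delta-F over S
    binding score and centre-distance co-localization percentage, whole-cell
    fluorescence traces with endocytosis-event detection, nearest-neighbour
    particle tracking with displacement and speed statistics, proximity
    ligation assay (PLA) signal counting per DAPI-defined cell, and three
    relative-quantification methods for qPCR Cq tables (delta-delta-Ct,
    efficiency-corrected Pfaffl, and a minimum-referenced Pfaffl variant).
    A synthetic-scene generator produces every input the pipeline consumes,
    with ground truth, so all stages can be validated without raw microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
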