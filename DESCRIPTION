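Package: nucmorph
Title: Nuclear Envelope Morphometry from Localized Nuclear Pore Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes fluorescently tagged nuclear pore complexes (NPCs) in 3D
    confocal stacks of budding-yeast nuclei with sub-voxel precision, corrects
    the axial elongation caused by refractive-index mismatch with a
    second-degree polynomial model fitted on round-nucleus subpopulations,
    partitions detections of non-spherical (mitotic) nuclei into 1-3 k-means
    clusters, reconstructs the nuclear envelope per cluster with an
    interpolating-subdivision model and an anchor-point model, and derives
    per-nucleus geometry (surface, volume, sphericity) together with
    population-level statistics: spindle-pole-body axis angles, cumulative
    frequency curves, and landmark-aligned kernel density maps of NPC and SPB
    positions. Includes a ground-truthed synthetic-data generator (parametric
    envelopes, aberration injection, image rendering) and a resumable pipeline
    with a command-line interface.
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
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
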