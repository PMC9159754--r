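Package: tissuecoords
Title: Organ-Centric Coordinates, Growth Tensors and Cell Measures for
    Segmented Tissue Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification toolkit for segmented cellular meshes of plant
    tissues, both 2.5D surface segmentations and full 3D cell complexes.
    Provides organ-centric coordinate systems (cell-distance fields, Bezier
    axis coordinates, polar and relative radial coordinates), per-cell
    direction frames, principal-directions-of-growth analysis of time-lapse
    pairs, cubic radial-basis-function deformation fields with analytic
    gradients for subcellular growth and semi-automatic lineage tracking,
    division-plane analysis in 2.5D and 3D, a catalogue of cell shape,
    network, signal and polarity measures, cell-type and layer
    classification, and a synthetic-tissue generator with known ground
    truth for testing every algorithm without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    e1071,
    mgcv,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
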