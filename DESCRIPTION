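Package: tomopict
Title: Deep-Learning Segmentation and Particle Localization for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A complete workflow for semantic segmentation and particle
    localization in cellular cryo-electron tomograms: amplitude-spectrum
    equalization pre-filtering, slice-wise 2D U-Net compartment segmentation,
    configurable 3D U-Net structure and particle segmentation, connected-
    component post-processing with contextual region filtering, filament
    centerline sampling, and detection/segmentation evaluation metrics with a
    tolerance radius. Includes a seeded synthetic tomographic phantom
    generator (spherical particles, hollow shells, membrane vesicles, missing
    wedge, additive noise) so the full pipeline can be exercised and tested
    without external data. Volumes are read and written as MRC2014, particle
    lists as CSV, and runs are orchestrated from YAML configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
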