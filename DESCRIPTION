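Package: synaptiq
Title: Synaptic Puncta Colocalization, Cortical Morphometry and Miniature
    Postsynaptic Current Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies structural and functional synapse measures from
    fluorescence microscopy and patch-clamp data. Segments pre- and
    post-synaptic puncta in confocal z-stacks and array-tomography section
    series by adaptive local thresholding, links footprints across sections
    into 3D objects, removes single-section artifacts with a consecutive-
    section persistence filter, pairs pre/post puncta by center distance
    into putative synapses and reports volumetric densities over neuropil
    regions of interest. Field-level morphometry covers cell densities,
    thresholded signal areas, axon line-crossing counts and perilesion band
    partitions. Miniature postsynaptic currents are detected by scaled
    template matching with recording quality control and summarised as
    frequency, amplitude and charge transfer. Seeded synthetic-data
    generators with full ground truth make every stage testable by
    parameter recovery.
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
    readr,
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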