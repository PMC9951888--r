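Package: stentmorph
Title: Rapid Morphological Measurement of Thoracic Aortic Stent-Grafts
Version: 0.1.0
Authors@R: person("stentmorph", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the follow-up deformation of thoracic aortic
    stent-grafts from CT volumes or binary stent masks. Segments the stent by
    Hounsfield-unit thresholding and connectivity, separates the zig-zag
    support rings, fits a cubic-spline centerline through the ring centroids,
    automatically extracts the peak (apex) observation points of every ring,
    registers point sets to a skeletal origin landmark, and computes end-slip
    vectors, characteristic ring diameters with ring rates, and ring
    deflection angles across imaging timepoints. A parametric voxel phantom
    generator with analytic apex ground truth makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
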