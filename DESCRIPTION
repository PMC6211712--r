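Package: focalseg
Title: Map-Algebra and Histogram-Based Segmentation of Fluorescence
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised, automated segmentation of single-channel
    fluorescence microscopy images of heterogeneous tissue, aimed at
    semi-quantitative pixel-intensity analysis of cell cytoplasm flanked
    by dim background and brightly stained blood vessels.  Implements
    map-algebra focal (neighborhood) operations on raster images,
    integrated-intensity first- and second-difference thresholding,
    fixed-percentile thresholding, and local Moran spatial
    autocorrelation masking, together with a validation battery
    (arithmetic perturbation tests, manual-versus-machine trend
    comparison by cosine similarity, z-stack consistency, distribution
    diagnostics) and a seeded generator of tripartite synthetic images
    with per-pixel ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
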