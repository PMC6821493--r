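Package: csmacq
Title: Quantification of cSMAC Formation in T Cell:APC Couples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatiotemporal image analysis of supramolecular protein
    accumulation at the immunological synapse. Provides a synthetic-data
    generator for 4D T cell:antigen-presenting-cell couple movies, STED-like
    puncta volumes and traced membrane polylines; standardization of
    segmented T cells onto a 6628-voxel half-spheroid template with
    interface-enrichment scoring; classification of interface accumulation
    into six mutually exclusive patterns (central, invagination, diffuse,
    lamellal, peripheral, asymmetric) and tabulation of pattern frequencies
    over the cell-coupling time course; 3D puncta segmentation with
    Otsu thresholding, distance-transform-seeded splitting and a
    control-derived size filter; membrane-undulation ratios from EM-section
    traces with the interface-quartering convention; and a statistics layer
    with two-proportion z-tests, power analysis, Chauvenet outlier
    rejection, log-transform ANOVA and hierarchical clustering of
    sensor-by-time frequency matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    ape
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
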