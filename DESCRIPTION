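Package: sproutquant
Title: Quantification of Endothelial Motility, Sprout Arbors and Vessel Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative analysis of endothelial cell behaviour in
    vitro and in vivo: displacement and speed statistics of tracked cells and
    sprout tips, a modified Sholl analysis that counts multicellular sprouts
    traversing concentric cylinders around a spheroid aggregate reconstructed
    from brightfield z-stacks segmented by local intensity variance, and
    morphometry of vessel networks (density, width, length) and gelatin
    degradation assays. Includes synthetic-data generators with exact ground
    truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    igraph,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
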