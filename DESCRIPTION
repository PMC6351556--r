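Package: clonefish
Title: Clonal Expansion and smFISH Dot Quantification for Dual-Reporter Lineage Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for lineage-tracing studies of tumour
    cells carrying a dual-fluorescence membrane reporter (mT/mG). Implements
    GFP+ clonal-area quantification from two-channel fluorescence images
    (threshold, binarize, pixel sums, GFP% = 100*B/(A-B)), clone detection and
    size-class statistics, saturating logarithmic growth-curve fitting with an
    exponential-decay alternative for model comparison, and a fully specified
    single-molecule FISH (RNAscope) dot-counting pipeline: pixel
    classification, one-pass 3x3 erosion, particle analysis with a
    circularity filter, cross-channel coincidence filtering, majority-surface
    per-cell dot assignment and per-population dot ratios. A ground-truthed
    synthetic tissue-scene generator (Voronoi epithelial sheet, membrane
    reporters, Poisson dot statistics, coincident speckles) makes every stage
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
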