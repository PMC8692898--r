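Package: serialihc
Title: Serial-Section IHC Registration and Tumor-Microenvironment Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial analysis of serially sectioned, single-marker
    immunohistochemistry (IHC) slides of gastric-cancer tissue. Serial sections
    are registered onto a reference (centroid) slide by downsampled affine plus
    demons-style nonrigid registration; deformation fields are upsampled and
    used to warp full-resolution images so that markers stained on different
    sections can be compared in one coordinate frame. Hematoxylin/DAB stain
    separation yields marker-positive masks, which are summarised per annotated
    compartment (tumor gland, invasive front, distal stroma, lymphoid nodule)
    and on a 1000x1000-pixel tile grid as density heatmaps, hotspot calls and
    tile-wise permutation tests of cross-marker colocalization. A companion
    expression module implements quality-control filtering of cell-by-gene
    matrices, a rank-based partial-EMT signature score with Wilcoxon group
    comparison, a Wilcoxon/Bonferroni/fold-change marker-gene rule and
    normality-gated group-fraction tests. A synthetic-data generator produces
    serial sections with known deformations, planted marker point processes and
    expression matrices with planted signature effects, providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
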