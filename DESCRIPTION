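Package: hestain
Title: Structure-Centric Color Normalization for H&E Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Color normalization for hematoxylin-and-eosin (H&E) stained
    histology tiles that anchors colors to tissue structures rather than to
    stain chemistry.  An image is reduced to a small palette by k-means in a
    Cartesian embedding of HSV space, palette colors are assigned to four
    tissue elements (white/lumen, stroma, nuclei, cytoplasm), a cascade of
    linear support vector machines classifies every pixel and records a
    signed hyperplane-distance certainty per class, and pixels are remapped
    onto standardized per-structure target colors while preserving each
    pixel's deviation about its structure mean.  Includes the accompanying
    evaluation toolkit (intra/inter-cluster variance diagnostic, inter- and
    intra-image variability, histogram mutual information and its noise
    calibration) and a synthetic H&E tile generator with ground-truth
    structure maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
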