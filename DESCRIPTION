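Package: pathograph
Title: Cell-Graph and Semantic-Feature Fusion for Histology Growth-Pattern Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-branch pipeline for classifying tissue growth patterns in
    histology tiles. Nucleus instances are encoded as polar-ray contours,
    summarised by shape, gray-level co-occurrence texture and local patch
    descriptors, and connected into a K-nearest-neighbour cell graph that a
    graph convolutional network embeds; a small VGG-style convolutional
    encoder embeds the whole tile; the two embeddings are combined by a
    gated Kronecker-product fusion head trained with cross-entropy. Includes
    a synthetic tile generator with class-specific spatial point processes,
    a classical watershed fallback segmenter, evaluation metrics, and
    slide-level quantification of pattern proportions in 5% increments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Matrix,
    methods,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
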