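Package: clusterDx
Title: Chunked Parallel K-Means Preprocessing for Ensemble Logistic
    Classification and Grid-Based Lesion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a chunked, merge-based parallel k-means used as a
    shared pre-processing stage for two diagnostic pipelines: (i) a
    weighted-ensemble logistic-regression classifier over tabular clinical
    data, with mean imputation, min-max normalization, cluster-distance
    outlier flagging and cluster-feature augmentation; and (ii) pixel
    intensity quantization of grayscale radiographs feeding a YOLO-style
    detection geometry (grid-cell responsibility, cell-relative box
    encoding, IoU, confidence, non-maximum suppression, anchor derivation)
    with an affected/non-affected image flagger. Includes seeded synthetic
    generators for both data kinds, confusion-matrix metrics, JSON/CSV/PNG
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
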