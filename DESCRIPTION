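Package: danet
Title: Divide-and-Attention Networks for H&E Pathological Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Divide-and-Attention Network (DANet) for
    classifying hematoxylin-and-eosin stained pathology image patches. A
    binary nuclei mask decomposes each patch into nuclei-only and
    non-nuclei images; five convolutional branches (original, nuclei,
    non-nuclei and two fused middle branches) learn features
    independently, a branch-selection attention module pools the five
    branch vectors, and a deep canonical correlation analysis (DCCA)
    penalty ties the fused branches to the tissue structure they
    emphasize. Includes non-overlapping patch tiling, confusion-matrix
    metrics and majority-voting aggregation, and a synthetic H&E image
    generator with exact ground-truth masks so the whole pipeline is
    testable on a laptop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
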