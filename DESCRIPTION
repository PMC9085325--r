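Package: ngramimg
Title: N-Gram Texture Features for Grayscale Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies grayscale medical images (ultrasound, OCT) by treating
    them as text: gray values are quantized into a 16-letter alphabet, row-wise
    n-gram tokens (n = 1, 2, 3) are extracted as a bag of visual words, token
    counts are weighted by term frequency (TF) or term frequency-relevance
    frequency (TF-RF), features are selected by a Wilcoxon rank-sum filter
    followed by expected cross-entropy ranking, and images are classified with
    cross-validated support-vector machines or a small multilayer perceptron,
    including a pairwise-voting ensemble for three-class problems. Ships a
    synthetic-data generator that plants class-discriminative horizontal
    gray-level motifs so the whole pipeline is testable without clinical data,
    plus optional preprocessing (Perona-Malik anisotropic diffusion,
    border-connected white-edge fill, longest-diameter rotation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
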