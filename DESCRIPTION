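Package: vhtrellis
Title: Virtual Hexagonal Trellis Features for White Blood Cell Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies white blood cell (leukocyte) smear images into the
    four major classes (eosinophil, lymphocyte, monocyte, neutrophil) using
    gradient texture features derived from a virtual hexagonal trellis
    overlaid on the square pixel grid. Provides the symbolic derivation of
    the trellis gradient kernels from virtual-element averaging, a
    convolution-based texture feature extractor, a pluggable deep-feature
    backend with a deterministic surrogate, ant colony optimization wrapper
    feature selection, serial feature fusion, a harness of support vector
    machine and nearest-neighbour classifier variants with a full one-vs-rest
    evaluation metric suite, and a seeded synthetic smear image generator so
    the whole pipeline runs and is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
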