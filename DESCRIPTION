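Package: mcdmbench
Title: Multi-Criteria Benchmarking of Binary Diagnostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks competing binary diagnostic classifiers by computing
    ten confusion-matrix-derived criteria per cross-validation fold,
    assembling a direction-aware normalized decision matrix, weighting
    criteria objectively by the entropy method, and ranking the classifiers
    with the PROMETHEE II outranking method, cross-validated by the VIKOR
    compromise ranking. Ships a fully transcribed case study of 19
    convolutional neural networks evaluated for melanoma diagnosis, a
    synthetic-classifier simulator with planted sensitivity/specificity for
    end-to-end testing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
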