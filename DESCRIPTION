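Package: crossviewrg
Title: Cross-View Attention and Visual-Semantic Recurrent Generation of
    Radiology Reports from Paired-View Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains and evaluates a multi-view medical report generation
    model at desk scale. Paired frontal/lateral grayscale images are encoded
    by two small convolutional backbones; a cross-view attention module
    recalibrates each view with shared squeeze-excitation gates and mixes the
    views by a convex combination, with single-view and cross-view multi-label
    classification branches tied together by a mean-squared-error consistency
    loss. Predicted lesion tags are embedded and fused with the two visual
    streams by three recurrent visual-semantic networks with additive
    attention; a hierarchical sentence/word LSTM decoder emits the report
    sentence by sentence under a learned stop control. Includes a seeded
    synthetic generator of paired-view studies with templated reports,
    from-scratch BLEU, ROUGE-L, CIDEr and macro-AUC metrics, a reverse-mode
    automatic differentiation tape the model is trained with, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
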