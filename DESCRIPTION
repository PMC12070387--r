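Package: twintower
Title: Twin-Tower Multimodal Fusion of Brain MRI and Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts binary therapy response of glioma patients from
    multi-sequence brain MRI and RNA-seq gene expression with a twin-tower
    architecture: a low-complexity convolutional encoder for tumor slices and
    an autoencoder bottleneck for expression profiles are trained separately
    on modality-exclusive samples, then frozen while a fusion head
    (feature concatenation or mixture-of-experts) is trained on the scarce
    dual-modality subset. Includes cohort ingestion (NIfTI volumes,
    transcript quantification tables, GTF annotation, clinical labels),
    maximum-tumor-slice extraction, seeded stratified splitting and
    cross-validation, confusion-matrix/ROC metrics, and a synthetic
    radiogenomic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    rtracklayer,
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
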