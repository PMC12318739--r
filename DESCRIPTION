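Package: noduleca
Title: Dual Cross-Attention Multimodal Classification of Pulmonary Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benign-malignant classification of pulmonary nodules by fusing
    radiologist-annotated structured attributes with 3D CT nodule volumes
    through a pair of cross-attention modules running in opposite directions
    (image queries over structured tokens and structured queries over image
    tokens). Includes LIDC-style cohort construction (size and reader-count
    selection, consensus label derivation, rounded-mean imputation of a
    missing fourth reader), CT volume preprocessing (isotropic resampling,
    cube extraction, Hounsfield windowing), transformer encoders for both
    modalities with hand-written reverse-mode gradients and AdamW training,
    stratified five-fold cross-validation, a confusion-matrix metric suite,
    and a synthetic nodule generator with controllable class separation so
    the whole pipeline is testable without protected imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    yaml,
    withr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    RNifti
Config/testthat/edition: 3
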