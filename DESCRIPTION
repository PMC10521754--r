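Package: mmil
Title: Multimodal Multiple Instance Learning for Lymph Node Metastasis
    Prediction from Histopathology Tiles and Serum Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary lymph-node-metastasis (LNM) status of colorectal
    cancer patients from two routinely available modalities: tiled
    hematoxylin-eosin histopathology images and four serum tumor biomarkers
    (CEA, CA125, CA19-9, AFP).  Each slide is treated as a bag of tiles in a
    multiple instance learning (MIL) formulation; tiles are embedded by a
    convolutional backbone, discriminative feature dimensions are selected by
    a histogram-compressed maximum mean discrepancy score, and a
    gated-attention pooling layer produces the slide representation.  The
    biomarker vector is imputed by chained equations with predictive mean
    matching, min-max normalised, and encoded by a feedforward network; the
    two representations are combined by gating-based attention and Kronecker
    tensor fusion before classification.  Includes a synthetic cohort
    generator with the statistical structure the pipeline assumes,
    cross-validation and fine-tuning protocols, ROC/Youden/bootstrap
    evaluation, tile-level probability heatmaps and a reduced histomic
    characterisation of high-probability tiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
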