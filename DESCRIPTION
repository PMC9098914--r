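Package: slnradiomics
Title: Ultrasound Radiomics Pipeline for Sentinel Lymph Node Status Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for predicting sentinel lymph node
    metastatic status in clinically negative breast cancer patients from
    primary-tumor ultrasound images and clinical variables. Provides marker
    inpainting, seeded region growing, peritumoral ring construction by
    morphological dilation, four-family texture radiomics (gray-level
    co-occurrence, run-length, size-zone and neighborhood gray-tone difference
    matrices; 134 named features), nearest-donor proximity imputation and
    univariate cohort statistics for clinical tables, genetic-algorithm feature
    selection with leave-one-out cross-validation selection frequencies,
    radial-basis-function support vector machine classification with
    prevalence-threshold metrics and bootstrap confidence intervals, and a
    soft-voting ensemble over clinical and radiomic models. A synthetic-data
    module generates speckle-textured phantom images, caliper marker overlays
    and clinical tables with controllable class effects so that every stage is
    exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
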