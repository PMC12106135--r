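Package: hemadapt
Title: Adapter-Based Vision-Transformer Segmentation of Hematoma on Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-efficient adapter fine-tuning pipeline for hematoma
    segmentation on non-contrast head CT. Provides Hounsfield-unit conversion
    and window/level contrast adjustment, orientation and size standardization,
    a promptable vision-transformer segmentation model with serial bottleneck
    adapters trained by a native reverse-mode autodiff engine, boundary-aware
    loss functions, slice- and scan-level segmentation metrics including the
    95th-percentile Hausdorff distance, stratified cross-validation with
    Friedman/Nemenyi model comparison, inter-observer agreement analysis binned
    by lesion size, and a synthetic head-CT phantom generator with a correlated
    second annotator so the whole pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
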