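Package: fibreprop
Title: Long-Range Fibre Proportion Analysis for Post-Stroke Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds volume-corrected, percentile-thresholded structural
    connectomes from raw streamline-count matrices, bands connections into
    short/medium/long range by inter-centroid distance quartiles, and computes
    the ratio of long-range to short-range fibres. Provides ROI-level
    univariate lesion-symptom mapping with one-tailed tests and
    Benjamini-Hochberg FDR control, derivation of a "key damage" covariate,
    covariate residualization, and residual-correlation variance partitioning
    (additional variance explained by the fibre proportion beyond age, years
    post stroke, lesion volume and key-region damage). Includes a synthetic
    lesion-cohort simulator with known ground truth for calibration and
    parameter-recovery studies, plus readers/writers and a run-all pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
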