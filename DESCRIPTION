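Package: fovsharp
Title: Objective Sharpness and Reader-Study Statistics for Paired-FOV CT Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial-resolution gain of small field-of-view (FOV)
    CT reconstructions over standard large-FOV reconstructions of the same raw
    data. Implements an automated per-slice image-sharpness metric (Otsu-based
    anatomy and bone segmentation, significant-edge selection on the gradient
    magnitude, cubic B-spline resampling of the large-FOV volume onto the
    small-FOV grid, gradient-magnitude sharpness scoring under identical masks)
    together with the companion reader-study statistics (ICC(2,k) interrater
    agreement, exact tie-aware Wilcoxon signed-rank and rank-sum tests, Likert
    score summaries). A synthetic-data module renders parametric leg CT
    phantoms with FOV-dependent reconstruction blur and simulates ordinal
    reader-rating tables, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    Matrix,
    RNifti,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
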