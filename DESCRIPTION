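Package: fluoroquant
Title: Objective Quantification of Dental Fluorosis from Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative light-induced fluorescence (QLF) analysis of dental
    fluorosis on the maxillary central incisors. Implements two
    lesion-reconstruction techniques operating on the green channel of 8-bit
    fluorescence images: a mask-aware unsharp-mask blur subtraction with
    2-standard-deviation pixel selection, and a three-dimensional convex-hull
    "clean surface" reconstruction with morphological opening and background
    thresholding. Provides automatic reference-area selection from a gingival
    triangulation point, per-tooth fluorosis metrics (Area, fluorescence loss
    dF, and the summary metric dQ), a seeded synthetic tooth-phantom generator
    with known ground truth and a dose-response population model, and the
    accompanying statistics: pairwise water-interval separation (Mann-Whitney
    with Bonferroni correction and the ANOVA/Levene decision path), Spearman
    rank correlation against photographic Thylstrup-Fejerskov scores,
    repeatability intraclass correlation, and ROC analysis with a Youden
    operating point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    png,
    jsonlite,
    ggplot2,
    generics,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
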