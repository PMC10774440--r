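Package: ccsplit
Title: Centrosome and Centriole Cohesion Scoring from Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for the centrosomal/centriolar (C/C)
    cohesion biomarker assay in blood-derived cells. Turns multi-channel
    fluorescence z-stacks of DAPI- and pericentrin-stained lymphoblastoid
    cells or peripheral blood mononuclear cells into per-cell split calls,
    per-sample splitting percentages and cohesion-deficit classifications;
    quantifies LRRK2-inhibitor reversal; normalizes multiplexed Western-blot
    band ratios against an internal-standard lane; and provides the cohort
    statistics layer (Shapiro-Wilk, one-way ANOVA with Tukey post-hoc,
    paired t, Spearman, ROC c-statistic). A synthetic-data module renders
    ground-truth-annotated images and cohort tables so the whole pipeline
    is verifiable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    tiff,
    xml2,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
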