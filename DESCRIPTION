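Package: metaboqc
Title: Post-Processing, Quality Metrics and Reference Ranges for
    Untargeted LC-MS Metabolomics and Preclinical Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical post-processing of untargeted LC-MS metabolomics
    feature tables exchanged in the three-file tabular convention
    (dataMatrix, sampleMetadata, variableMetadata): blank-ratio filtering,
    dilution-series correlation filtering, loess signal-drift correction
    against pooled QC or biological reference samples, pooled-QC
    coefficient-of-variation filtering, collapsing of chemically redundant
    features (isotopes, adducts, in-source fragments) and final log2
    transformation, with full feature-count bookkeeping. Provides five
    dataset-level quality metrics on a 0-100 scale (Drift Spearman, Drift
    PCA, QC spread, QC CV, QC ICC), spiked-standard outlier screening, a
    seeded synthetic-data generator with recorded ground truth for
    validating the pipeline, and rr95 reference-range estimation with
    Shapiro-Wilk-gated transformation selection for preclinical
    phenotyping variables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
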