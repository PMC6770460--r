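Package: crossmir
Title: Cross-Over Analysis of Circulating miRNA Expression and Endurance
    Training Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for randomized cross-over studies of
    blood-borne microRNA expression measured on microarrays. Covers quality
    control and quantile normalization with detection and expression filters,
    Spearman-based sample outlier removal, principal component and principal
    variance component analysis (PVCA), pooled and treatment-group pre/post
    differential expression with volcano categorization, z-score wave
    clustering of temporal profiles, elastic-net regression of maximal oxygen
    uptake (VO2 max) on miRNA expression with repeated grouped
    cross-validation, and a carbohydrate-recommendation procedure that
    classifies participants by their per-period VO2 max response and screens
    for discriminating marker miRNAs. A synthetic-data generator with planted
    ground truth emulates the study design so every stage is testable without
    any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    limma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
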