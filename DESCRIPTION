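Package: fermnet
Title: Microbiome-Volatile Association Analysis for Spontaneous
    Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking microbial community succession to volatile
    compound dynamics in spontaneously fermented foods and beverages.
    Provides alpha-diversity estimators (Chao1, Shannon, Gini-Simpson,
    Good's coverage) and stage-wise OTU set summaries, PCA ordination with
    a deterministic sign convention, odor-activity-value (OAV) scoring and
    banding of volatiles against odor thresholds, thresholded correlation
    (co-occurrence) networks with exact t-based p-values, a from-scratch
    NIPALS PLS2 engine with VIP variable-importance scores and
    leave-one-out component selection, and a three-criteria screen that
    identifies the core functional microbiota and its bipartite
    association network with volatiles. A seeded synthetic-data generator
    with planted microbe-to-volatile effects provides ground truth for
    every stage. Ships the published flat-peach-wine volatile table as a
    worked fixture.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
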