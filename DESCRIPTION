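Package: dysbiotyper
Title: Dysbiosis Typing and Hierarchical Classification of Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for relating gut microbial
    community composition to diagnosis-based patient groups. Provides
    unsupervised dysbiosis typing (partitioning around medoids on
    Bray-Curtis dissimilarities with silhouette-guided choice of k),
    LEfSe-style differential abundance scoring (Kruskal-Wallis screen plus
    a bootstrapped linear-discriminant effect size), hierarchical
    multi-label classification with Random Forest ensembles of predictive
    clustering trees evaluated by per-node AUPRC and delta-AUPRC over
    host-only baselines, and a Dirichlet-multinomial synthetic-cohort
    generator so the whole pipeline runs without external data.
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
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
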