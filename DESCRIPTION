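Package: sagetrend
Title: LongSAGE Tag Filtering, Exact Differential Expression and
    Expression-Trend Clustering for Progression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for serial analysis of gene expression (LongSAGE)
    progression atlases: extraction of 17-base tags from ditag reads,
    the bad-tag / quality-factor / linker-derived-tag filter cascade with
    per-library composition accounting, Audic-Claverie exact tests for
    count differences between libraries with a cross-replicate
    consistency rule, Poisson-deviance K-means consensus clustering of
    three-stage expression trends with amalgamation into five major
    trend groups, EASE-score category enrichment, Pearson 1-r library
    trees, principal-component signature projection, and a ground-truthed
    synthetic atlas generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
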