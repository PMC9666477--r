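Package: hetree
Title: Tree-Based Representation and Stratification of Intra-Tumor Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents the multi-lesion disease of a cancer patient as a merge tree
    (an average-linkage dendrogram over reduced radiomic lesion profiles) and compares
    patients with a measure-weighted pruned tree edit distance. Provides view-aware
    principal component reduction of radiomic feature tables, per-patient dendrogram
    construction, an exact merge-tree edit distance (exhaustive mapping oracle plus an
    optimized branch-and-bound solver), the pruning operator and its exact breakpoint
    integration against a Beta or discrete weighting measure, cohort-level ward
    clustering with silhouette-based model selection, density-based noise checks,
    single-lesion and mean-profile baselines, clinical characterization test batteries,
    height-count curve summaries with permutation inference, Kaplan-Meier group
    comparison, and seeded synthetic cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
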