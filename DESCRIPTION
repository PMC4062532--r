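Package: neurexmap
Title: Brain-Wide Expression Clustering, Coordinate-Based Meta-Analysis and
    Set-Based Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An imaging-transcriptomics pipeline linking regional brain
    gene-expression profiles to structural neuroimaging findings and to
    set-based genetic association. Provides per-gene Z-normalisation,
    nearest-neighbour (single-linkage) hierarchical clustering with a
    two-donor consensus rule, cluster mean-Z voxel maps with hemisphere
    folding and Gaussian blurring, activation likelihood estimation (ALE)
    coordinate-based meta-analysis with a random-foci permutation null and
    FDR control, an empirical random voxel-pair distance null for testing
    anatomical proximity, correlation-ranked gene sets, and a
    phenotype-permutation set-based association test with LD-based
    informative-marker selection. A seeded synthetic-data generator emulates
    the statistical structure of the inputs (regional expression with
    planted spatially smooth clusters, study foci tables, LD-blocked
    case/control genotypes) so the whole pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    cluster,
    igraph,
    mclust,
    ape,
    IRanges,
    S4Vectors,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
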