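Package: SeascapeScales
Title: Scale-Explicit Seascape Genetics with Spatial Eigenvector Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Attributes SNP allele-frequency variation across a seascape to
    environment, geographic isolation and directional larval dispersal at
    explicit spatial scales. Builds distance-based Moran's eigenvector maps
    (db-MEMs) from geographic distances and asymmetric eigenvector maps
    (AEMs) from directed larval-connectivity matrices, estimates the
    characteristic spatial scale of every eigenvector, and fits per-locus
    all-subsets multiple regressions summarised by Akaike-weight variable
    importances, nested likelihood-ratio tests and nonparametric importance
    comparisons. Includes pool-based pairwise FST, Mantel isolation-by-
    distance tests, least-cost marine distances over a land/sea raster, and
    a synthetic-seascape generator with planted spatial structure for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    igraph,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Regression, Spatial
RoxygenNote: 7.3.3
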