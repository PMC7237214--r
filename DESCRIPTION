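Package: rarescape
Title: Rarity and Phylogenetic Rarity Analysis of Soil Invertebrate
    Metabarcoding Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of land-use impacts on soil invertebrate
    communities profiled by DNA metabarcoding. Provides tag-jump (index
    hopping) decontamination by through-origin quantile regression,
    taxonomic filtering and group assignment, six per-sample biodiversity
    metrics (richness, effective species numbers, occurrence-weighted
    rarity, Faith phylogenetic diversity, phylogenetic endemism, and mean
    pairwise distance) with standardized effect sizes against a regional
    null model, community-structure analyses (Jaccard and unweighted
    UniFrac distances, NMDS, PERMANOVA, multivariate dispersion, mean
    pairwise beta diversity), stratified bootstrap comparison of the
    land-use variance explained by each metric, and a synthetic community
    generator with planted land-use structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
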