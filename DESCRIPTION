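Package: popsphere
Title: Contrastive Spherical Embeddings of SNP Genotype Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised dimensionality reduction of diploid SNP genotype
    matrices for population-structure visualization. Samples are embedded on
    the 3D unit sphere by a convolutional encoder trained with a centroid-based
    N-pair contrastive loss, using genotype-specific data augmentation (allele
    flips and missingness masking) to generate positive pairs. Includes readers
    for PLINK binary and EIGENSTRAT formats, minor-allele-frequency and
    sex-chromosome filters, a hierarchical Balding-Nichols population
    simulator with a SNP-chip missingness experiment, the Equal Earth map
    projection for 2D visualization of the sphere, and a suite of
    KNN-based embedding quality metrics (local, global and generalization
    scores, neighbor overlap, neighbor rank RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: DimensionReduction, SNP, PopulationGenetics, Visualization
RoxygenNote: 7.3.3
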