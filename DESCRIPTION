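Package: haplopaint
Title: Haplotype-Based Diversity, Differentiation and In-Silico Chromosome
    Painting for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing SNP genotype panels of inbred (effectively
    homozygous) crop lines: intensity-based genotype calling, missingness and
    minor-allele-frequency filters, LD-kNN imputation, sliding-window haplotype
    diversity (haplotype heterozygosity and effective number of haplotypes),
    pairwise linkage disequilibrium with a background (unlinked) threshold and
    LD-decay block size, LD-based effective population size, Weir-Cockerham
    Fst, AMOVA, Nei distance with neighbour-joining trees, PCA, donor-panel
    curation with a resampling null, and a haploid Li-Stephens copying-model
    HMM that paints recipient genomes as mosaics of geographically defined
    donor subpopulations with replicate-consensus ancestry assignment and
    deviant-region detection.  A synthetic-data module generates differentiated
    donor subpopulations, mosaic recipients with recorded truth, Wright-Fisher
    drift panels and two-channel intensity clouds so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
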