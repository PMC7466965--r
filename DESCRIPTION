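Package: brewtrace
Title: Comparative Genomics and Phenotyping Toolkit for Polyploid Brewing Yeast
Version: 0.1.0
Authors@R:
    person("Brewtrace", "Developers", email = "brewtrace@example.org",
           role = c("aut", "cre"))
Description: Analyses for characterizing polyploid industrial yeast isolates
    against a reference genome: ploidy inference from flow-cytometry DNA
    content and SNP allele-frequency spectra, genotype filtering and
    relatedness estimation (identity by state, KING kinship, neighbor
    joining, PCA), divergence dating of closely related strains from shared
    synonymous variants under a molecular clock, read-depth CNV calling with
    kinship-pruned frequency estimation, structural-variant call-set
    comparison with closest-call proximity statistics, split-read
    translocation scanning with a simulation-based power study, and
    sliding-window growth-rate extraction from plate-reader curves. Every
    input class can be generated synthetically so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    ape,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
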