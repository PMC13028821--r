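Package: komagenomics
Title: Comparative Genomics of Complete Komagataeibacter Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for comparative analysis of complete
    Komagataeibacter assemblies: curated genome manifests, MinHash
    sketching and Mash distance estimation with neighbor-joining trees,
    plasmid homology clustering with backbone-versus-mosaic conservation
    classification, cellulose-synthesis (bcs) locus anchoring with
    c-di-GMP neighborhood features and principal component projection,
    insertion-sequence and prophage burden summaries, pangenome
    core/accessory/singleton composition metrics, and cross-module
    Spearman correlation linkage with false-discovery-rate control.
    Includes a seeded synthetic-genome generator with machine-readable
    ground truth so every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    igraph,
    ape,
    Biostrings,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
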