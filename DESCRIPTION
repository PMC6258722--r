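Package: spaceqtl
Title: Spatial eQTL Mapping from Hi-C Contacts with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns disease-associated SNPs to the genes they regulate by
    joining restriction-fragment Hi-C contact lists with per-tissue
    genotype-expression association testing. Identifies SNP-gene pairs whose
    fragments physically contact in the nucleus, tests each pair for eQTL
    effects in every tissue with an additive linear model, controls the false
    discovery rate by Benjamini-Hochberg, and classifies associations as cis
    (within 1 Mb of the transcription start site) or trans. Supporting
    statistics include a Monte Carlo random-SNP-set enrichment null, a Fisher
    exact cis:trans contrast for regulatory SNPs, per-tissue HLA contribution
    summaries, pairwise linkage-disequilibrium R-squared profiling, and
    hypergeometric gene-set enrichment. A synthetic-data module generates
    genomes, fragments, genotypes, contacts and multi-tissue expression with
    planted eQTL effects so every stage is verifiable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
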