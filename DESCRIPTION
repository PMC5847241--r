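Package: mirsnp
Title: Allele-Specific miRNA Target-Site Prediction and Pedigree Genotype QC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pattern-based prediction of microRNA target sites in 3'UTR
    sequences that evaluates both alleles of UTR SNPs and reports which
    allele is predicted to bind miRNAs more strongly. Implements
    Teiresias-style (L,W) maximal pattern discovery over a mature-miRNA
    corpus, Markov-background significance filtering, target-island calling
    by windowed pattern-hit enrichment, antiparallel complementarity duplex
    alignment with G:U wobble and affine gaps, and per-SNP classification
    (stronger allele, equal binding, island without alignment, no island).
    Also provides the companion pedigree genotype-cleaning stage:
    completion-rate, monomorphism, Mendelian-error-rate and exact
    Hardy-Weinberg filters, plus detection and removal of trio genotypes
    causing Mendelian errors. Includes seeded synthetic-fixture generators
    (miRNA corpora with planted motifs, UTRs with planted allele-sensitive
    target sites, pedigrees with injected Mendelian errors) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
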