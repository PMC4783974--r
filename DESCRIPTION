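Package: qtlsnp
Title: Mining and Validating Candidate-Gene SNPs Around Growth QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for mining single nucleotide polymorphisms (SNPs) in
    candidate genes from transcriptome pileups aligned to a draft genome,
    co-localizing those genes with quantitative trait locus (QTL) markers
    on a scaffold-anchored genetic map, selecting a one-SNP-per-gene assay
    panel, and validating the panel in a population sample with standard
    population-genetic statistics: minor allele frequency, observed and
    unbiased expected heterozygosity, the fixation index, exact
    Hardy-Weinberg tests by complete enumeration, and genotypic linkage
    disequilibrium G-tests against a permutation null.  A synthetic-data
    generator produces genomes, strand-aware gene models, pileups, map and
    QTL tables and genotype matrices with known ground truth, so every
    stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
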