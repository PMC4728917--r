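Package: rarehap
Title: Rare-Allele Haplotype Discovery and Evolutionary Rates from
    Multi-Accession Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers distinct haplotypes in per-locus multiple alignments of
    many accessions of one species by a fixed-substitution criterion, classifies
    alleles and SNPs (gSNP, nfSNP, dSNP), polarizes substitutions and indels as
    derived or ancient against an aligned outgroup, and computes the associated
    population-genetic statistics: relative evolutionary rates, a random
    occurrence model for rare alleles, the unfolded site frequency spectrum with
    its neutral expectation and frequency excess, quadratic extrapolation to
    fixation, between-species divergence (Dxy), Tajima's D, codon effects and
    transition/transversion ratios.  A seeded coalescent-style generator
    produces synthetic datasets with a full ground-truth ledger for every
    downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
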