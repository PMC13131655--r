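Package: notoscan
Title: Quantifying Haplotype Variation, Transposon Dynamics and Conserved
    Elements in Notothenioid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval-level analytics for comparative genomics of the
    notothenioid (Antarctic fish) radiation: heterozygous transposable-element
    insertion calling between assembly haplotypes by reciprocal overlap,
    mixed-model association of structural variants with local genomic
    features against shuffled controls, dated repeat landscapes from
    Kimura divergences under a neutral substitution rate, per-branch genome
    gain/loss rates and transposon-insertion attribution on a dated species
    tree, conserved-element ancestry classification from per-species
    alignment-depth tracks, gene-tree monophyly filters for selection scans,
    and structural analytics of tandem antifreeze-glycoprotein gene loci.
    A synthetic-data generator with fully known planted truth makes every
    stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
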