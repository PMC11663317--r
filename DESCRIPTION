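Package: c9methyl
Title: Methylation, Length and Purity of C9orf72 Repeat Expansions from
    Targeted Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted, amplification-free long-read
    (HiFi) sequencing of the C9orf72 GGGGCC hexanucleotide repeat expansion.
    Assigns on-target reads to the wild-type or expanded allele by k-means
    clustering of k-mer counts, summarises per-CpG 5mC methylation scores
    (0-255) into per-read and per-sample metrics, measures repeat length,
    somatic length variability and GGGGCC sequence purity, and runs the
    cohort association layer (Spearman correlations, paired and unpaired
    Wilcoxon tests, age-adjusted regression, longitudinal stability and
    familial transmission classification). Includes a synthetic-read
    generator that emulates the statistical structure of a targeted HiFi
    cohort, so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    broom,
    dplyr,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
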