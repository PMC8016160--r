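Package: cleanroomr
Title: Metagenomic Profiling and Decision Rules for Spacecraft-Assembly Cleanrooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for low-biomass metagenomic surveillance of controlled
    environments such as spacecraft-assembly cleanrooms. Reads classified-read
    report tables (including the KrakenUniq report dialect with unique marker
    k-mer statistics), applies evidence thresholds and a negative-control
    contamination rule to taxonomic assignments, computes k-mer complexity QC
    statistics from FASTQ reads, summarises alpha and beta diversity with
    analytic rarefaction, annotates taxa with survival-relevant traits
    (spore formation, radiation and desiccation resistance, psychrophily),
    screens metagenome-assembled genomes by completeness and contamination,
    and estimates bacterial replication rates from peak-to-trough coverage
    ratios on circular genomes. A seeded synthetic-data generator emulates
    every input with known ground truth so the whole pipeline is testable
    without raw sequencing data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
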