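Package: repliquant
Title: Quantification of Replication Origin Activity from Early S-Phase
    Sequencing Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for quantifying replication origin firing in
    budding yeast from coverage tracks of BrdU immunoprecipitation
    sequencing (QBU) and chromatin immunoprecipitation sequencing
    (ChIP-seq) experiments performed in hydroxyurea-arrested early S
    phase.  Provides readers for chrom.sizes, BED and bedGraph files;
    fixed-width binning with median smoothing, replicate averaging and
    cross-strain scale normalization; classification of origin groups
    (confirmed, Fkh-activated, Fkh1-sensitive, rDNA, centromere-proximal
    by the nearest-flanking rule); per-origin window statistics, strain
    difference tables, group distribution summaries with Welch t-tests,
    peak width estimation and feature-centered heatmap matrices.  Also
    includes a stochastic simulator of origin firing under a limiting
    initiation-kinase pool with pathway-specific recruitment boosts,
    used to generate realistic synthetic experiments for testing and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
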