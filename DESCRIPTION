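Package: sagrad
Title: Simulation and Evaluation of Single-Cell RAD Sequencing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate restriction-site-associated DNA sequencing
    (RADseq) from single amplified genomes (SAG-RAD). Provides a paired-end
    read simulator with known ground truth that emulates single-digest RAD
    library geometry and the coverage bias of multiple displacement
    amplification (lognormal per-locus amplification, allelic dropout,
    contamination, PCR duplicates); inline-barcode demultiplexing with
    read-level quality filters; a de-novo locus assembler in the style of
    the stacks/catalog/matching workflow with coverage-based locus filters
    and insert-length PCR deduplication; per-sample quality-control metrics
    (locus counts, Lorenz/Gini coverage uniformity, depth distributions,
    bulk concordance, heterozygosity, allelic-dropout rate, replicate
    sharing); and a nearest-haplotype coancestry matrix with hierarchical
    clustering to score recovery of population structure. All functions
    take and return tidy data frames so complete in-silico experiments can
    be composed with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
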