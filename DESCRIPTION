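Package: cafs
Title: Chromosome-Scale Assembly by FISH Walking with Conserved Synteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromosome-scale genome assembly studies in species
    with telocentric karyotypes: sliding-window gene-density and GC tracks,
    a gene-density "ridge" clustering statistic tested against a permutation
    null, regional Spearman scans of the GC/gene-density correlation, the
    Cafs strategy (chromosome assembly by FISH walking assisted by conserved
    synteny) for grouping, ordering and orienting scaffolds from simulated
    fluorescence in situ hybridization evidence and tri-species synteny
    anchors, and assembly summary statistics (Nxx tables, k-mer genome-size
    estimation, per-chromosome reports). A synthetic-data module simulates
    genomes, annotations, scaffold tilings, synteny maps, FISH measurements
    and read sets so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
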