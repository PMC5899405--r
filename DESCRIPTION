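Package: capmeth
Title: Dual-Purpose Targeted Capture Genotyping and Methylation Analysis
    for Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dual-purpose targeted sequence-capture
    experiments in polyploids, where one capture is split and sequenced both
    untreated (genotype) and bisulphite-treated (methylome). Implements
    capture probe-set design (tiling, annotation, ranking, GC boosting),
    pileup-based polyploid SNP calling, homoeologous-SNP-driven assignment of
    reads and methylation calls to sub-genomes, per-cytosine methylation
    extraction with CpG/CHG/CHH context classification, genotype-aware
    correction of the reference cytosine set, bisulphite conversion-efficiency
    estimation on an unmethylated control genome, pairwise Fisher exact
    differential methylation, and capture-efficiency reporting. A bundled
    synthetic polyploid genome and read simulator makes every stage testable
    end to end without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
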