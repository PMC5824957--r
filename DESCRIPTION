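Package: clonesoma
Title: Somatic Mutation Discovery and Aging Inference from Single-Cell-Derived Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of in-vivo somatic variants from single-cell-derived
    clone versus blood sequencing callsets, with false-negative-rate estimation
    and burden correction, trinucleotide mutational-signature extraction and
    refitting, regional enrichment and depletion testing with gene-set
    resampling nulls, and inference of age-related mutation accumulation rates
    and proliferation thresholds. Includes a synthetic-data simulator that
    generates reference sequences, multi-sample callsets, region sets and
    clone metadata with the statistical structure the analysis assumes, so
    every stage can be exercised without access to protected sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    rtracklayer,
    MASS,
    lme4,
    lmerTest,
    pracma,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
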