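Package: retrozyme
Title: Discovery and Annotation of Hammerhead-Ribozyme Retrozymes in Genomic Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hammerhead ribozyme (HHR) motifs in genomic DNA with a
    descriptor-based secondary-structure grammar, groups hits into tandem-repeat
    retrozyme loci (monomer period, copy number, GC content, target-site
    duplications), clusters loci into sequence families, fits first-order
    self-cleavage kinetics (F_t = F_inf(1 - exp(-k t))), scores self-pairedness of
    monomer RNAs with a maximum base-pairing fold, and ships a seeded synthetic
    genome generator with planted retrozyme arrays so every stage of the pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
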