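Package: sheepmir
Title: Characterization of the Sheep Left-Ventricle miRNAome from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for the post-detection characterization of
    novel microRNA precursors discovered by small RNA sequencing of sheep
    (Ovis aries) left ventricle and a pooled multi-tissue library. Implements
    signal-to-noise score-cutoff selection and candidate retention filters,
    conservation tiering from homology hit tables with deterministic
    miRBase-style nomenclature, isomiR classification (templated and
    non-templated 5'/3' variants, polymorphic forms), arm-preference and
    arm-switching analysis, grouping of precursors sharing a mature sequence,
    genomic cluster detection and per-chromosome density, median-of-ratios
    normalization with no-replicate fold change, and stem-loop qRT-PCR
    relative quantification (2^-dCt against U6). A synthetic-data generator
    emulates two-library read stacks on hairpin precursors with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
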