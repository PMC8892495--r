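Package: xrseqr
Title: Simulation and Analysis of XR-Seq Excision-Repair Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nucleotide excision repair from XR-seq
    (excision-repair sequencing) data: excision-product length
    distributions, per-position nucleotide frequency matrices, dual
    incision-site geometry inference, damage-signature detection, and
    strand-resolved transcription-coupled repair (TCR) metrics via
    unit-gene TS/NTS meta-profiles, per-gene Log2(TS/NTS) and
    time-courses. Includes a synthetic-data generator that emulates
    damage formation at dipyrimidine (CPD/(6-4)PP) or GpG (cisplatin)
    motifs, fixed incision offsets and expression-dependent
    template-strand repair enhancement, with full ground-truth tables so
    every pipeline stage is verifiable by parameter recovery, plus a
    sequence-derived expected-damage-site landscape module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    rlang,
    data.table,
    ggplot2,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
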