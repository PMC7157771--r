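Package: tnta
Title: Detection and Analysis of Toxin-Antitoxin Modules in Tn3 Family Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting Tn3-family transposition modules that
    carry type II toxin-antitoxin (TA) gene pairs in bacterial sequence data.
    Calls open reading frames, screens their translations against a labeled
    reference protein library with local alignment, clusters passing hits into
    candidate transposition modules, renders gene-arrangement configuration
    strings, predicts res resolution sites (subsites I, II, III) and the
    crossover AT dinucleotide, detects intertransposon recombination
    breakpoints at res site I with a change-point statistic on windowed
    identity profiles, counts independent TA-acquisition events on
    neighbor-joining toxin trees, and aggregates catalogs of TA-carrying
    transposons. Includes a synthetic-data generator that plants modules,
    res sites, and chimeric junctions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
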