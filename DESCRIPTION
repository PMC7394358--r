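Package: irscan
Title: Gene-Anchored Inverted-Repeat Detection for Phase-Variable Type I
    Restriction-Modification Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects all maximal, 100%-identity inverted repeats of at
    least a configurable minimum length (default 20 bp) between an
    annotated specificity gene (hsdS) of a Type I
    restriction-modification system and its genomic flanks (default 30 kb
    each side), classifies loci as inverting versus incidental by whether
    the repeat partner lies in a second annotated hsdS gene, segments
    hsdS genes into target recognition domains (TRDs) between the
    repeats, and enumerates the hsdS allele space and the
    population-level methyltransferase state space such shufflon loci can
    generate. Includes a dynamic-programming brute-force oracle for the
    repeat search, a deterministic synthetic-genome generator that plants
    inverting loci and decoy repeats with ground truth, and a command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    tools,
    utils,
    stats,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
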