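Package: tc1scout
Title: Discovery and Characterization of IS630/Tc1/mariner DNA Transposons
Version: 0.1.0
Authors@R:
    person("tc1scout", "developers", email = "tc1scout@example.org",
           role = c("aut", "cre"))
Description: Structure-based identification and characterization of
    IS630/Tc1/mariner DNA transposons in genome assemblies. Implements the
    three-point evidence rule for element calling (identical terminal
    inverted repeats, TA target-site-duplication excision sites, and a
    transposase open reading frame), DDE catalytic-triad detection with
    spacing-class nomenclature (DD34E, DD40E, ...), frameshift repair of
    broken transposase ORFs by minimal insertion removal, genome-wide
    full-length copy census with solo-TIR scanning, element boundary
    inference from homolog presence/absence groups, amino-acid composition
    profiling with Pearson-correlation proteome ranking, and neighbor-joining
    phylogeny of DDE domains. A synthetic-genome simulator with planted
    elements and ground-truth annotations makes the whole pipeline testable
    without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
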