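Package: ribopes
Title: Translatome Profiling, 5' Pyrimidine Motif Enrichment, HDX-MS Uptake
    and Equilibrium Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for the computational arms of a
    tRNA-fragment translational-control study: ribosome-profiling quality
    control (P-site offset estimation, trinucleotide periodicity, region-level
    RPKM, codon occupancy), translational-efficiency computation and
    differential-translation calling, classification of 5' terminal
    oligopyrimidine (TOP) and pyrimidine-enriched sequence (PES) motifs with
    hypergeometric enrichment testing, differential deuterium-uptake analysis
    for hydrogen-deuterium exchange mass spectrometry (HDX-MS), and
    equilibrium binding-curve fitting. Every input class can be generated by
    seeded simulators with planted ground truth, so parameter recovery is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
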