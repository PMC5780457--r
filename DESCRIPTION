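Package: radmut
Title: Mutation Spectrum and Sequence-Context Analysis for Radiation
    Mutagenesis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing mutations induced by
    ionizing radiation in whole-genome re-sequenced mutant cohorts.
    Implements allele-frequency-based filtering and zygosity assignment of
    per-sample variant calls, merging of proximal calls into complex
    mutation events, seven-category classification with deletion size
    binning, sequence-context annotation of indels (homopolymer runs,
    polynucleotide repeats, junction microhomology), prediction of
    non-synonymous gene impacts from gene models, and group-level
    statistics (per-bp mutation frequency, merged substitution spectrum
    and Ti/Tv, heterozygous:homozygous ratios against the Mendelian M2
    expectation, per-locus mutation frequency arithmetic, and single-hit
    multitarget survival curve fitting).  A synthetic mutagenesis
    simulator generates reference genomes, gene models, ground-truth
    mutations and noisy per-sample call sets so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
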