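Package: rrlpopgen
Title: Reduced-Representation Library Design, Genotype Calling and
    Population-Genomic Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reduced-representation library (RRL) population
    genomics: in-silico restriction digestion of a genome with blunt-end
    cutters and fragment-size selection, a synthetic two-population diploid
    read-count simulator with known truth, genotype calling from allelic
    read counts by fixed allele-balance cut-offs or by binomial genotype
    likelihoods, population-based SNP filtering, multi-caller overlap and
    genotype-concordance analysis with validation scoring, and
    allele-frequency-differential sliding-window scans for divergent
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
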