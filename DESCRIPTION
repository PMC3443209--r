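Package: tlrpop
Title: Toll-Like Receptor Diversity Analysis for Bottlenecked Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-nucleotide polymorphism diversity at
    Toll-like receptor (TLR) amplicons in small, pedigreed wildlife
    populations. Implements codon-level classification of substitutions,
    IUPAC-coded Sanger genotype handling, Mendelian inference of unsampled
    founder genotypes from offspring, pedigree-assisted haplotype phasing,
    detection of coamplifying gene duplicates (paralogs) from universal
    heterozygosity and clone experiments, multinomial clone-sampling design
    calculations, small-sample diversity statistics (observed
    heterozygosity, Nei's unbiased gene diversity, exact Hardy-Weinberg
    tests by full enumeration, nucleotide diversity), and McDonald-Kreitman
    tests of selection. A seeded synthetic-data generator produces every
    input the pipeline consumes together with ground truth, emulating a
    12-founder bottlenecked bird population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
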