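Package: ystrkit
Title: Forensic Y-STR Population Genetics: Diversity Parameters, AMOVA/Rst,
    MDS and Haplogroup Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal short tandem repeat (Y-STR)
    population data. Reads haplotype tables on standard locus panels (Minimal
    haplotype, PowerPlex Y12, Yfiler 17, PowerPlex Y23) with micro-variant
    allele designations and the multi-copy DYS385a/b locus, applies the
    complete-profile filter, and computes the standard forensic summary
    parameters: per-locus allele frequencies, gene diversity, polymorphic
    information content, match probability and power of discrimination, plus
    haplotype diversity and discrimination capacity. Between populations it
    estimates pairwise Rst by analysis of molecular variance (AMOVA) on
    squared repeat-count distances with permutation p-values, and embeds the
    resulting distance matrix by classical multidimensional scaling. A
    Bayesian classifier assigns Y haplogroups from per-haplogroup allele
    frequency tables. A stepwise-mutation-model population simulator generates
    realistic singleton-heavy Y-STR datasets so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
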