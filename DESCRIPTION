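Package: triadquant
Title: Homoeolog-Aware Quantitative Proteomics and Promoter Haplotype
    Analysis for Allohexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing quantitative proteomics data from
    allohexaploid bread wheat in a subgenome-resolved way: exact-identity
    peptide-to-proteome matching against an A/B/D-partitioned protein
    database, assignment of proteins to specific homoeologs, calling of
    phosphate-deficiency-responsive proteins (PDRPs) from isobaric
    reporter intensities with fold-change thresholds, and tests of
    homoeolog expression balance. A second arm covers promoter population
    genetics: SNP calling on aligned promoter panels, Nei-Li nucleotide
    diversity, haplotype grouping, haplotype-trait association with
    Duncan's multiple range test, and in-silico CAPS marker design by
    restriction digestion. A synthetic-data module generates all inputs
    with the statistical structure the analyses assume, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
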