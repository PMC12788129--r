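Package: hybmeth
Title: Methylome Inheritance and Allele-Specific Expression Analysis for F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite methylation calls of a
    parent/parent/F1 hybrid trio: global methylome profiles and bisulfite
    conversion-rate estimation, sliding-window differential methylation with
    Fisher exact tests, per-site methylation inheritance classification into
    eight categories, parent-specific SNP (PSNP) based allelic expression
    imbalance calling with TMM normalisation and a negative-binomial exact
    test, five-rule identification of parent-specific methylation sites
    (PSMSs), and integration of allele-specific methylation with allelic
    expression. Includes a ground-truthed synthetic trio generator so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
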