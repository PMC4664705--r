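Package: badscan
Title: Window-Based DMR Calling and Megabase Methylation Domain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares whole-genome bisulfite sequencing methylomes between
    two conditions with replicates. Tiles the genome into 300 bp windows,
    tests pooled methylated/unmethylated read counts with Fisher's exact
    test under Benjamini-Hochberg FDR control, and calls differentially
    methylated regions (DMRs) that show a reproducible methylation
    difference of at least 25 percent in both replicates. Downstream
    stages compute genomic-element enrichment of DMRs with a permutation
    test, methylation-band shift tables, 0.5 Mb binning of DMRs into
    differentially methylated domains via a top-quartile rule, domain
    overlap statistics against lamina-associated domains (hypergeometric
    test), occupancy-domain correlation, and DMR-to-gene association
    within flanking windows. A seeded synthetic-methylome generator with
    planted domains supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
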