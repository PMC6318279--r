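Package: allelix
Title: Allele-Specific Epigenome and 3D-Genome Analysis of the Inactive X
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for allele-specific analysis of the inactive X chromosome
    in hybrid cells: SNP-based partitioning of sequencing reads between
    parental haplotypes, binned allelic count tracks, ChIP enrichment and
    H3K27me3 depletion-domain calling, CpG methylation summaries, allelic
    expression classification of X-linked genes, Hi-C contact-matrix
    balancing (Knight-Ruiz), insulation scores, A/B compartment
    eigenvectors, TAD re-establishment scoring, Repli-seq replication-timing
    Z-scores, and the rank-based region contrasts tying the assays together.
    Includes a fully specified synthetic diploid chromosome generator with
    planted ground truth for validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
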