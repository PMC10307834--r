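Package: hlameth
Title: SNP-Aware Methylation Array Probe Auditing and HLA-Region
    Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rigorous DNA methylation analysis of the highly
    polymorphic HLA region on Infinium-style methylation arrays. Classifies
    the influence of population SNPs on each array probe (ONSITE / 5nt /
    10nt windows relative to the probe 3' end, for all four strand-by-design
    cases), flags probes unreliable at configurable minor-allele-frequency
    thresholds, runs region-restricted case-control differential methylation
    testing with detection-P filtering, HLA-DQB1*06:02 carrier adjustment
    and Bonferroni correction, and compares allele-level HLA expression via
    length-normalized per-million transcript abundances. Includes a full
    synthetic-data generator with a ground-truth ledger and a command-line
    pipeline driver, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
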