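Package: acghcnv
Title: Copy Number Variant Discovery and Population CNVR Catalogs from
    Array CGH Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Self-self-calibrated copy number variant (CNV) calling from
    array comparative genomic hybridization (aCGH) log2-ratio profiles,
    aggregation of CNVs into copy number variable regions (CNVRs),
    classification of CNVRs as line-fixed or line-specific across a
    structured population, interval-overlap statistics against external
    CNV sets, and relative copy-number quantification from qPCR threshold
    cycles. Includes a synthetic aCGH cohort generator (probe maps,
    implanted CNVs with known truth, self-self replicate arrays) so the
    whole pipeline is testable without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
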