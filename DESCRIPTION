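Package: multicom
Title: Reproducibility-Consensus SNP Selection and Candidate-Gene Discovery
Version: 1.0.0
Authors@R: person("Ramesh", "Devel", email = "devel@example.org", role = c("aut", "cre"))
Description: Ensemble consensus selection of single-nucleotide polymorphisms
    across multiple variant callers (keep calls reproduced by at least k of n
    tools), with the downstream candidate-discovery chain used in targeted
    resequencing studies of contrasted phenotype groups: depth/quality VCF
    filtering, transition/transversion quality diagnostics, group-specific
    variant derivation, interval-based gene and region annotation, partition of
    candidate genes against reference QTL gene lists, hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction, overlap with differential
    expression tables, sequencing run-metric summaries, and a seeded synthetic
    multi-caller callset simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
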