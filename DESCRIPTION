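Package: cisrank
Title: Ranking-and-Recovery Enrichment Analysis of Cis-Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a genome-wide database of candidate regulatory regions
    (CRRs) from heterogeneous feature tracks, scores and ranks every region
    for transcription-factor binding motifs (via a cis-regulatory-module
    scorer with cross-genome order-statistic rank aggregation) and for
    experimental tracks (ChIP-seq, DNase/FAIRE peaks or coverage), and
    identifies the features most enriched in a user-supplied set of regions
    or genes by a GSEA-like ranking-and-recovery analysis: area under the
    top-ranked recovery curve, normalized enrichment scores, and
    leading-edge selection of direct target regions. Includes motif-to-TF
    annotation, SSD-based motif clustering with Calinski-Harabasz model
    selection, nearest-gene assignment, report/BED/SIF writers, and a
    deterministic synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
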