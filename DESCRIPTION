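Package: marscan
Title: Genome-Wide Characterization of Matrix Attachment Regions
Version: 0.1.0
Authors@R:
    person("MAR", "Analysis", email = "marscan@example.org", role = c("aut", "cre"))
Description: Tools to characterize genome-wide maps of matrix attachment
    regions (MARs), the genomic anchor points of chromatin loops on the
    nuclear matrix. Reconciles replicate peak sets into common MAR
    intervals, computes interval-level statistics (size distributions,
    inter-MAR midpoint distances, per-chromosome densities), scans MAR
    sequences for classic MAR signatures (the ATC rule, origin-of-
    replication motifs, AT-rich stretches, curved and kinked DNA,
    topoisomerase II sites), detects and canonicalizes simple sequence
    repeats (501 non-redundant unit classes, 1-6 bp), associates MARs
    with transposable elements by local alignment, classifies MARs
    against gene annotation (UTR/exon/intron/intergenic, TSS
    metaprofiles, paused Pol II promoters, chromatin-domain boundaries),
    and generates fully self-contained synthetic universes with planted
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
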