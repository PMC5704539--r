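Package: scgbaits
Title: Single-Copy Ortholog Discovery and Hybridization Bait Design from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated workflow for target-enrichment marker
    development in non-model plants. Putative orthologous single-copy genes
    are discovered from heterogeneous de novo transcriptome assemblies by
    translated homology search against a two-species single-copy-gene
    reference, cleaned of host contaminants, paralogs, and redundancy, and
    turned into tiled 120-bp hybridization baits with exon-aware splitting,
    identity clustering, and organelle off-target screening. Includes a
    desk-scale gapped/ungapped local search engine, a reference-anchored
    locus aligner with an optional MAFFT backend, and a planted-truth
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: mafft (optional, for the external alignment backend)
Config/testthat/edition: 3
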