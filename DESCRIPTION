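Package: iecreg
Title: Cross-Species Analysis of Conserved Intestinal Epithelial Transcriptional Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting transcriptional regulation that is conserved
    across vertebrate intestinal epithelial cells (IECs). Provides ortholog-anchored
    integration of expression matrices with PCA-based tissue signature calling,
    matching of anteroposterior expression gradients between the zebrafish and mouse
    intestine (z-scoring, uncentered-correlation clustering, 4-to-7 segment
    interpolation, correlation filtering), accessibility-based classification of
    transcription start sites and conserved nonexonic elements from peak sets and
    signal tracks, position weight matrix promoter scanning with motif co-occurrence
    and hypergeometric enrichment, AT-content metaprofiles, and a fully labelled
    synthetic four-species cohort generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    zoo,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
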