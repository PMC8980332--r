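Package: crmscan
Title: Prescreening and Design of Cell-Type-Specific Cis-Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates putative cis-regulatory modules (CRMs) from chromatin
    accessibility coverage, scores them by the density of cell-type-enriched
    transcription factor binding sites (TFBSs), and classifies likely-active
    CRMs on a two-threshold density plot. Includes JASPAR position frequency
    matrix parsing and double-strand log-odds motif scanning, tandem-repeat
    masking, marker gene and TF selection from clustered single-cell count
    matrices via Wilcoxon rank-sum tests, a designer for synthetic "stitched"
    CRMs assembled from accessible regions under the AAV packaging budget,
    and simulators that generate every pipeline input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
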