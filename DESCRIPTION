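Package: arescan
Title: Scanning Gene Regulatory Regions for Antioxidant Response Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers putative antioxidant response element (ARE) sequences
    in gene regulatory regions. Builds strand-aware promoter windows by
    extending transcripts upstream of the transcription start site,
    intersects them with transcription-factor ChIP-seq peaks, scores the
    resulting segments on both strands with a log2-odds position-specific
    scoring matrix derived from a JASPAR position frequency matrix with
    pseudocounts, retains sites whose relative score meets a cutoff, and
    annotates them with candidate cis-regulatory element (cCRE) segmentation
    labels. Includes a synthetic-data generator that plants motif instances
    with oracle-computed scores so every pipeline stage can be tested
    without external downloads.
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
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
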