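Package: nucshift
Title: Nucleosome Positioning, Shift Statistics and Cryptic Transcription
    Signatures from Chromatin Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for genome-wide chromatin profiling in
    budding yeast: normalizes tiling-array probe intensities and paired-end
    mononucleosome fragment midpoints into occupancy tracks, calls nucleosome
    center positions with a Gaussian-filter peak caller, quantifies signed
    shifts of genic nucleosomes relative to the transcription start site
    against a wild-type reference panel, segments strand-specific
    differentially transcribed regions (transfrags) from expression tracks,
    and scans for combined chromatin-plus-expression signatures such as
    transcripts de-repressed together with upstream nucleosome loss and
    promoter-associated transcripts. A synthetic-data generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
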