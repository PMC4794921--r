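Package: nfkbmap
Title: Combinatorial NF-kB Cistrome and Knockdown Transcriptome Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multi-subunit NF-kB ChIP-seq cistromes (p50, p52,
    RelA, RelB) with knockdown transcriptomes and a lymphoma expression
    panel. Unifies per-subunit peak sets into an occupancy matrix with
    4-bit combinatorial pattern codes, clusters summit-centered signal
    profiles, assigns binding regions to genes through promoter windows
    and chromatin loops, calls regulated genes from a four-group
    knockdown design (Welch t-tests with Benjamini-Hochberg control and
    a minimum expression-difference rule), defines direct target genes,
    fits logistic regression models predicting regulation mode from
    distance-stratified subunit binding patterns with bootstrap
    stability scoring, and scores concordance of direct targets with
    Hodgkin-lymphoma-versus-rest differential expression. Includes a
    synthetic-data generator with planted ground truth so the whole
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    rtracklayer,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
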