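Package: bacplex
Title: Multiplex BAC Shotgun Assembly Post-Processing, Scaffolding and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling bacterial artificial chromosome (BAC) clones
    sequenced in multiplex on short-read instruments. Implements paired-end read
    quality control with host and vector screening around the cloning site,
    post-processing of per-clone draft contigs (vector clipping with BAC-end
    flagging, read-back coverage, trimmed-mean coverage filtering of
    cross-contamination, contaminant screening), Nextera mate-pair preprocessing
    (duplicate removal, junction-adapter clipping), deconvolution of unbarcoded
    mate pairs by unique mapping, iterative link-graph scaffolding with gap
    estimation, and assembly evaluation (misassembly breakpoint classification,
    genome fraction, k-mer repeat masking, identity-stratified repeat overlap).
    A deterministic simulator generates complete synthetic BAC sequencing
    experiments with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
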