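Package: CNEscan
Title: Conserved Noncoding Element Discovery and Cross-Species Binding-Site Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovery of candidate cis-regulatory elements in orthologous
    noncoding DNA. Extracts noncoding sequence from annotated loci, computes
    global affine-gap pairwise alignments (with optional banding, or import of
    precomputed alignments), calls conserved regions by sliding-window percent
    identity with an identity-plus-length score, scans conserved sequence for
    transcription factor binding sites with IUPAC consensus and position-count
    matrix models on both strands, pairs orthologous sites through the
    alignment into a conserved-TFBS report, and ships a synthetic ortholog
    simulator with planted conserved blocks and motif instances so every stage
    is benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
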