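Package: wmdemux
Title: Watermark DNA Barcodes Robust to Insertions and Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and demultiplexing of synchronizing DNA barcodes built as
    concatenated watermark codes. An outer linear block code over a Galois
    field GF(q1) is combined with a sparse quaternary inner code and a shared
    watermark sequence, so that every barcode is a small perturbation of the
    watermark. A hidden Markov model over insertion/deletion drift states
    locates barcodes embedded in unknown sequence context and decodes them by
    forward-backward synchronization, symbol-wise posterior computation and
    soft maximum-likelihood outer decoding. Includes a randomized barcode-set
    designer under GC-content, homopolymer and self-complementarity
    constraints, a quaternary indel channel simulator with ground truth, and
    an evaluation harness for decoding-error estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
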