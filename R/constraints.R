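#' Biological sequence constraints for barcodes
#'
#' A barcode is experimentally usable only if (i) its GC content lies in
#' \[0.40, 0.60\] (bounds inclusive), (ii) it contains no homopolymer run
#' longer than 2 (no base repeated more than twice in a row), and (iii) it
#' is not equal to its own reverse complement (perfect self-complementarity
#' would let the oligo fold back or dimerize). Reverse complementation uses
#' the standard pairing A-T, C-G.
#'
#' @param b a DNA string over \{A, C, G, T\} (case-insensitive).
#' @return list with `pass` (logical) and `violated` (character vector with
#'   entries among `"gc"`, `"homopolymer"`, `"self_complement"`).
#' @examples
#' passes_constraints("ACGTTGCATG")
#' passes_constraints("AAATTT")   # fails gc and homopolymer
#' @export
passes_constraints <- function(b) {
  v <- dna_map(b)
  m <- .filter_matrix(matrix(v, ncol = 1L))
  violated <- c("gc", "homopolymer", "self_complement")[c(m$gc[1L], m$homo[1L], m$selfc[1L])]
  list(pass = m$pass[1L], violated = violated)
}

# vectorized constraint check on an N x M matrix of Z4 columns (one barcode
# per column); returns per-rule violation flags -- this is the designer's
# hot path
.filter_matrix <- function(bmat) {
  N <- nrow(bmat)
  gcf <- colMeans(bmat == 1L | bmat == 2L)
  bad_gc <- gcf < 0.40 | gcf > 0.60
  if (N >= 3L) {
    eq <- bmat[-1L, , drop = FALSE] == bmat[-N, , drop = FALSE]
    bad_homo <- colSums(eq[-1L, , drop = FALSE] & eq[-(N - 1L), , drop = FALSE]) > 0L
  } else {
    bad_homo <- rep(FALSE, ncol(bmat))
  }
  # complement of x is 3 - x under A=0, C=1, G=2, T=3
  rc <- 3L - bmat[N:1L, , drop = FALSE]
  bad_selfc <- colSums(bmat == rc) == N
  list(pass = !(bad_gc | bad_homo | bad_selfc),
       gc = bad_gc, homo = bad_homo, selfc = bad_selfc)
}

#' Levenshtein edit distance between DNA strings
#'
#' Unit-cost insertions, deletions and substitutions (dynamic programming
#' via [utils::adist()]). The edit metric is what the indel channel
#' effectively acts in; it is upper-bounded by the Hamming distance for
#' equal-length strings.
#'
#' @param a,b DNA strings.
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Edit-distance statistics of a barcode set
#'
#' Mean pairwise edit distance over ordered pairs,
#' `d_E = (1 / (n (n - 1))) * sum_{i != j} d_E(b_i, b_j)`, and the edit
#' distance distribution `D_e = #\{(i, j) : i != j, d_E(b_i, b_j) = e\} / M`
#' with `M = n (n - 1)`, so `sum_e D_e = 1`.
#'
#' @param set a `barcode_set` or a character vector of at least 2 barcodes.
#' @return list with `mean` (mean edit distance) and `distribution` (named
#'   numeric vector; names are the distances `e`).
#' @export
distance_stats <- function(set) {
  b <- if (inherits(set, "barcode_set")) set$barcodes else set
  stopifnot(is.character(b))
  if (length(b) < 2L) stop("need at least 2 barcodes for distance statistics")
  d <- utils::adist(b)
  off <- d[lower.tri(d)]           # each unordered pair once; ordered pairs double both
  tab <- table(off)
  list(mean = mean(off),
       distribution = stats::setNames(as.numeric(tab) / length(off), names(tab)))
}

#' Apply the sequence constraints to a barcode set
#'
#' Keeps the barcodes passing [passes_constraints()]; survivors retain their
#' original message indices. The report counts, per rule, how many input
#' barcodes violate it (a barcode violating several rules is counted once
#' under each, but excluded only once).
#'
#' @param set a `barcode_set`.
#' @return list with `set` (filtered `barcode_set`) and `report` (class
#'   `filter_report`: list with `input`, `surviving`, `excluded`, per-rule
#'   counts `gc`, `homopolymer`, `self_complement`, and `surviving_indices`).
#' @export
filter_set <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  bmat <- vapply(set$barcodes, dna_map, integer(nchar(set$barcodes[1L])),
                 USE.NAMES = FALSE)
  m <- .filter_matrix(bmat)
  report <- structure(list(
    input = length(set$barcodes),
    surviving = sum(m$pass),
    excluded = sum(!m$pass),
    gc = sum(m$gc),
    homopolymer = sum(m$homo),
    self_complement = sum(m$selfc),
    surviving_indices = set$indices[m$pass]
  ), class = "filter_report")
  out <- set
  out$barcodes <- set$barcodes[m$pass]
  out$indices <- set$indices[m$pass]
  out$filter_report <- report
  list(set = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Constraint filter: ", x$surviving, "/", x$input, " barcodes kept (",
      "gc: ", x$gc, ", homopolymer: ", x$homopolymer,
      ", self-complement: ", x$self_complement, " violations)\n", sep = "")
  invisible(x)
}
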