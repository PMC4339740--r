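#' DNA / Z4 mapping
#'
#' Fixed bijection between nucleotides and the integers modulo 4:
#' A = 0, C = 1, G = 2, T = 3. All barcode arithmetic (watermark addition,
#' channel substitution matrices, HMM emissions) is carried out on Z4 under
#' this mapping. Input is case-insensitive.
#'
#' @param seq a DNA string over \{A, C, G, T\}.
#' @return `dna_map`: integer vector over 0..3; `dna_unmap`: DNA string.
#' @examples
#' dna_map("ACGT")          # 0 1 2 3
#' dna_unmap(c(3L, 0L))     # "TA"
#' @export
dna_map <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T")) - 1L
  if (anyNA(v)) stop("sequence contains non-ACGT symbols")
  v
}

#' @rdname dna_map
#' @param v integer vector over 0..3.
#' @export
dna_unmap <- function(v) {
  if (any(v != as.integer(v)) || any(v < 0L) || any(v > 3L)) {
    stop("symbols outside Z4")
  }
  paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

# read symbols for the decoder: ACGT -> 0..3, N/ambiguity codes -> -1
# (treated as uniform-emission wildcards)
.dna_map_wild <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v <- match(ch, c("A", "C", "G", "T")) - 1L
  v[is.na(v)] <- -1L
  v
}

#' Sample a sparse inner code
#'
#' Draws `q1` distinct nonzero words of length `n2` over Z4, indexed by the
#' field elements `0 .. q1-1`. Sparsity keeps the shared watermark visible
#' through the assembled barcodes, which is what makes HMM synchronization
#' work, so sampling prefers the lowest Hamming weights: the weight-1 pool
#' (3*n2 words) is drawn from first and topped up from the weight-2 pool
#' only when `q1` exceeds it. The resulting mean density must stay below
#' `density_bound`.
#'
#' @param q1 inner code cardinality (= outer field order).
#' @param n2 inner word length.
#' @param density_bound maximal admissible mean density (default 0.3).
#' @return object of class `inner_code`: list with `q1`, `n2`, `words`
#'   (q1 x n2 integer matrix over Z4, row i = word for field element i-1)
#'   and `density`.
#' @export
sample_inner_code <- function(q1, n2, density_bound = 0.3) {
  q1 <- as.integer(q1); n2 <- as.integer(n2)
  stopifnot(q1 >= 2L, n2 >= 1L)
  dmin <- min_inner_density(q1, n2)
  if (is.na(dmin)) {
    stop("not enough nonzero words of weight <= 2: q1 = ", q1,
         " exceeds the pool for n2 = ", n2)
  }
  if (dmin >= density_bound) {
    stop("density bound ", density_bound, " unreachable for (q1, n2) = (",
         q1, ", ", n2, "): minimum achievable density is ", round(dmin, 4))
  }
  p1 <- .weight1_pool(n2)
  n1p <- nrow(p1)
  if (q1 <= n1p) {
    words <- p1[sample.int(n1p, q1), , drop = FALSE]
  } else {
    p2 <- .weight2_pool(n2)
    words <- rbind(p1, p2[sample.int(nrow(p2), q1 - n1p), , drop = FALSE])
  }
  new_inner_code(words)
}

#' @rdname sample_inner_code
#' @param words q1 x n2 integer matrix of distinct nonzero Z4 words.
#' @export
new_inner_code <- function(words) {
  stopifnot(is.matrix(words))
  storage.mode(words) <- "integer"
  if (any(words < 0L) || any(words > 3L)) stop("inner words must be over Z4")
  if (any(rowSums(words != 0L) == 0L)) stop("the all-zeros inner word is not allowed")
  if (anyDuplicated(apply(words, 1L, paste, collapse = ","))) {
    stop("inner code words must be distinct")
  }
  structure(list(q1 = nrow(words), n2 = ncol(words), words = words,
                 density = mean(words != 0L)),
            class = "inner_code")
}

.weight1_pool <- function(n2) {
  out <- matrix(0L, 3L * n2, n2)
  k <- 1L
  for (pos in seq_len(n2)) {
    for (v in 1:3) {
      out[k, pos] <- v
      k <- k + 1L
    }
  }
  out
}

.weight2_pool <- function(n2) {
  if (n2 < 2L) return(matrix(0L, 0L, n2))
  pairs <- utils::combn(n2, 2L)
  out <- matrix(0L, ncol(pairs) * 9L, n2)
  k <- 1L
  for (j in seq_len(ncol(pairs))) {
    for (v1 in 1:3) for (v2 in 1:3) {
      out[k, pairs[1L, j]] <- v1
      out[k, pairs[2L, j]] <- v2
      k <- k + 1L
    }
  }
  out
}

#' Minimum achievable inner density
#'
#' Mean density of the `q1` lowest-weight nonzero words of length `n2`
#' (weights 1 then 2). `NA` if fewer than `q1` such words exist.
#'
#' @inheritParams sample_inner_code
#' @export
min_inner_density <- function(q1, n2) {
  pool1 <- 3L * n2
  pool2 <- if (n2 >= 2L) 9L * choose(n2, 2L) else 0L
  if (q1 > pool1 + pool2) return(NA_real_)
  w1 <- min(q1, pool1)
  (w1 + 2 * (q1 - w1)) / (n2 * q1)
}

#' Mean density (mean Hamming weight) of an inner code
#'
#' `(1 / (n2 * q1)) * sum of word weights`; the fraction of nonzero symbols.
#'
#' @param code an `inner_code`.
#' @export
inner_density <- function(code) {
  stopifnot(inherits(code, "inner_code"))
  mean(code$words != 0L)
}

#' Pooled symbol prior of an inner code
#'
#' Relative frequency of each Z4 symbol over all inner words and positions.
#' Under the iid working assumption this is the distribution of the sparse
#' perturbation a barcode applies to the watermark at any one position;
#' `prior[1]` (the zero symbol) equals `1 - density`.
#'
#' @param code an `inner_code`.
#' @return numeric vector of length 4 summing to 1.
#' @export
symbol_prior <- function(code) {
  stopifnot(inherits(code, "inner_code"))
  tabulate(as.vector(code$words) + 1L, nbins = 4L) / (code$q1 * code$n2)
}

#' Effective substitution matrix of watermark transmission
#'
#' Viewing the barcode as the watermark corrupted by the inner words, the
#' inner code acts as an upstream substitution channel with matrix
#' `S'(b, w) = prior[(b - w) mod 4]`. Composing with the sequencing
#' substitution matrix gives the effective matrix
#' `E(r, w) = sum_b S(r, b) S'(b, w)` used by the boundary-estimation HMM.
#'
#' @param S 4 x 4 column-stochastic substitution matrix, `S[r, t] =
#'   P(receive r | sent t)` with rows/columns in A, C, G, T order.
#' @param inner an `inner_code`.
#' @return 4 x 4 column-stochastic matrix E.
#' @export
effective_substitution <- function(S, inner) {
  .check_stochastic(S)
  prior <- symbol_prior(inner)
  idx <- outer(0:3, 0:3, function(b, w) (b - w) %% 4L)
  Sp <- matrix(prior[idx + 1L], 4L, 4L)
  S %*% Sp
}

.check_stochastic <- function(S) {
  if (!is.matrix(S) || !all(dim(S) == c(4L, 4L))) stop("S must be 4 x 4")
  if (any(S < 0) || any(abs(colSums(S) - 1) > 1e-8)) {
    stop("S must be column-stochastic (columns sum to 1)")
  }
  invisible(S)
}

#' Draw a uniform random watermark
#'
#' @param N watermark length (= n1 * n2).
#' @return integer vector over Z4 of length N.
#' @export
random_watermark <- function(N) {
  sample.int(4L, N, replace = TRUE) - 1L
}

#' Assemble a barcode from a message
#'
#' Encodes the message with the outer code, maps each outer symbol to its
#' sparse inner word, concatenates to the inner block `s`, and adds the
#' watermark symbol-wise modulo 4: `b = s + w (mod 4)`, returned as DNA.
#'
#' @param msg integer message of `k1` field elements.
#' @param outer an `outer_code`.
#' @param inner an `inner_code` with `inner$q1 == outer$field$q`.
#' @param w watermark: integer vector over Z4 of length `n1 * n2`.
#' @return DNA barcode string of length `N = n1 * n2`.
#' @export
assemble_barcode <- function(msg, outer, inner, w) {
  stopifnot(inherits(outer, "outer_code"), inherits(inner, "inner_code"))
  if (inner$q1 != outer$field$q) stop("inner code cardinality != outer field order")
  N <- outer$n1 * inner$n2
  if (length(w) != N) stop("watermark length ", length(w), " != n1 * n2 = ", N)
  d <- encode_outer(outer, msg)
  s <- as.vector(t(inner$words[d + 1L, , drop = FALSE]))
  dna_unmap((s + as.integer(w)) %% 4L)
}

#' @export
print.inner_code <- function(x, ...) {
  cat("Inner code: ", x$q1, " words of length ", x$n2,
      " over Z4, density ", round(x$density, 3), "\n", sep = "")
  invisible(x)
}
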