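#' Outer linear block codes over GF(q1)
#'
#' Builds the outer code C1\[GF(q1), n1, k1\] of the concatenated barcode
#' construction. For lengths `n1 <= q1 + 1` an (extended) Reed-Solomon code
#' is constructed, which is MDS: its minimum Hamming distance attains the
#' Singleton bound `d_H = n1 - k1 + 1`. For the few admissible
#' configurations with `n1 > q1 + 1` a built-in registry of generator
#' matrices with documented minimum distance is consulted. In either case
#' the minimum distance is re-verified by exhaustive enumeration of all
#' `q1^k1` codewords, which is feasible for every supported configuration.
#'
#' The generator matrix is reduced to systematic form `G = [I | P]`, so the
#' first `k1` symbols of every codeword equal the message.
#'
#' @param q1 field order (2, 3, 4, 5, 7, 8 or 9).
#' @param n1 code length, `n1 > k1`.
#' @param k1 code dimension, `1 <= k1 < n1`.
#' @return an object of class `outer_code`: list with `field`
#'   (`galois_field`), `n1`, `k1`, `G` (k1 x n1 systematic generator
#'   matrix), `d_H` (verified minimum Hamming distance), `rate`
#'   (`k1/n1`), `codebook` (q1^k1 x n1 matrix of all codewords, row order =
#'   lexicographic message order) and `construction` (`"mds"` or
#'   `"registry"`).
#' @examples
#' oc <- build_outer_code(8, 6, 3)
#' oc$d_H   # 4: Singleton bound for a [6,3] MDS code
#' @export
build_outer_code <- function(q1, n1, k1) {
  n1 <- as.integer(n1); k1 <- as.integer(k1)
  if (k1 < 1L || k1 >= n1) stop("need 1 <= k1 < n1 (outer code must carry redundancy)")
  field <- galois_field(q1)
  q1 <- field$q
  if (q1^k1 > 1e6) stop("codebook too large for exhaustive distance verification")
  if (n1 <= q1 + 1L) {
    G <- .rs_generator(field, n1, k1)
    construction <- "mds"
    claimed_d <- n1 - k1 + 1L
  } else {
    entry <- .registry_lookup(q1, n1, k1)
    if (is.null(entry)) {
      stop("no code construction available for (q1,n1,k1) = (",
           q1, ",", n1, ",", k1, "): n1 > q1 + 1 and no registry entry")
    }
    G <- entry$G
    construction <- "registry"
    claimed_d <- entry$d_H
  }
  G <- .ff_systematize(field, G)
  msgs <- .all_messages(q1, k1)
  codebook <- .ff_matmul(field, msgs, G)
  d_H <- min(rowSums(codebook[-1L, , drop = FALSE] != 0L))
  if (d_H != claimed_d) {
    stop("distance verification failed for (", q1, ",", n1, ",", k1,
         "): enumerated d_H = ", d_H, ", expected ", claimed_d)
  }
  structure(list(field = field, n1 = n1, k1 = k1, G = G, d_H = as.integer(d_H),
                 rate = k1 / n1, codebook = codebook, construction = construction),
            class = "outer_code")
}

# Reed-Solomon generator: evaluate message polynomials of degree < k at n
# distinct points; for n = q + 1 the extra column evaluates "at infinity"
# (leading coefficient). Any k columns are independent, hence MDS.
.rs_generator <- function(field, n, k) {
  q <- field$q
  npts <- min(n, q)
  G <- matrix(0L, k, n)
  for (j in seq_len(npts)) {
    a <- j - 1L               # evaluation point = element j-1
    pw <- 0L                  # a^0 ... computed iteratively
    acc <- 1L
    for (i in seq_len(k)) {
      G[i, j] <- acc
      acc <- field$mul[acc + 1L, a + 1L]
    }
  }
  if (n == q + 1L) G[k, n] <- 1L
  G
}

# Gaussian elimination to systematic form [I | P]; the first k columns must
# be invertible (true for RS and for all shipped registry matrices).
.ff_systematize <- function(field, G) {
  G <- G
  k <- nrow(G)
  for (col in seq_len(k)) {
    piv <- which(G[col:k, col] != 0L)
    if (length(piv) == 0L) stop("generator matrix not systematizable in place")
    piv <- piv[1L] + col - 1L
    if (piv != col) G[c(col, piv), ] <- G[c(piv, col), ]
    inv <- field$inv[G[col, col] + 1L]
    G[col, ] <- field$mul[cbind(G[col, ] + 1L, inv + 1L)]
    for (r in seq_len(k)) {
      if (r != col && G[r, col] != 0L) {
        f <- G[r, col]
        sub <- field$mul[cbind(G[col, ] + 1L, f + 1L)]
        G[r, ] <- field$add[cbind(G[r, ] + 1L, field$neg[sub + 1L] + 1L)]
      }
    }
  }
  G
}

# all q^k messages as rows, lexicographic (first symbol most significant)
.all_messages <- function(q, k) {
  idx <- 0:(q^k - 1L)
  out <- matrix(0L, length(idx), k)
  for (j in seq_len(k)) {
    out[, j] <- (idx %/% q^(k - j)) %% q
  }
  storage.mode(out) <- "integer"
  out
}

.registry_cache <- new.env(parent = emptyenv())

.registry_lookup <- function(q1, n1, k1) {
  key <- "registry"
  if (is.null(.registry_cache[[key]])) {
    path <- system.file("extdata", "outer_code_registry.json", package = "wmdemux")
    if (!nzchar(path)) return(NULL)
    .registry_cache[[key]] <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  for (e in .registry_cache[[key]]) {
    if (e$q1 == q1 && e$n1 == n1 && e$k1 == k1) {
      G <- do.call(rbind, lapply(e$G, as.integer))
      return(list(G = G, d_H = as.integer(e$d_H)))
    }
  }
  NULL
}

#' Encode a message with the outer code
#'
#' @param code an `outer_code`.
#' @param msg integer vector of `k1` field elements.
#' @return integer vector of `n1` field elements `msg . G`; the first `k1`
#'   symbols equal `msg` (systematic form).
#' @export
encode_outer <- function(code, msg) {
  stopifnot(inherits(code, "outer_code"))
  if (length(msg) != code$k1) {
    stop("message length ", length(msg), " != k1 = ", code$k1)
  }
  q <- code$field$q
  if (any(msg != as.integer(msg)) || any(msg < 0) || any(msg >= q)) {
    stop("message symbols outside 0..", q - 1L)
  }
  drop(.ff_matmul(code$field, matrix(as.integer(msg), 1L), code$G))
}

#' Minimum Hamming distance of an outer code
#'
#' Exhaustive minimum nonzero-codeword weight; for linear codes this equals
#' the minimum pairwise Hamming distance.
#'
#' @param code an `outer_code`.
#' @return integer minimum distance.
#' @export
min_distance <- function(code) {
  stopifnot(inherits(code, "outer_code"))
  as.integer(min(rowSums(code$codebook[-1L, , drop = FALSE] != 0L)))
}

#' Soft maximum-likelihood decoding of the outer code
#'
#' Scores every codeword `d` by the log-likelihood
#' `sum_j log posteriors[j, d_j + 1]` and returns the best message. The
#' codebook never exceeds 1000 words for admissible configurations, so the
#' search is exhaustive by design. Ties are broken towards the smallest
#' message index (lexicographic message order).
#'
#' @param code an `outer_code`.
#' @param posteriors `n1 x q1` matrix of per-symbol probabilities (rows need
#'   not be normalized, but must be non-negative with a positive entry).
#' @return list with `message` (integer vector of k1 symbols), `index`
#'   (0-based message index), `codeword`, and `score` (log-likelihood).
#' @export
ml_soft_decode <- function(code, posteriors) {
  stopifnot(inherits(code, "outer_code"))
  q <- code$field$q
  if (!is.matrix(posteriors) || nrow(posteriors) != code$n1 || ncol(posteriors) != q) {
    stop("posteriors must be an n1 x q1 matrix")
  }
  if (any(posteriors < 0)) stop("negative posterior")
  if (any(rowSums(posteriors) == 0)) stop("degenerate posteriors: all-zero row")
  lp <- log(posteriors)
  cb <- code$codebook
  m <- nrow(cb)
  idx <- cbind(rep(seq_len(code$n1), each = m), as.vector(cb) + 1L)
  scores <- rowSums(matrix(lp[idx], m, code$n1))
  best <- which.max(scores)   # first maximum = smallest message index
  list(message = .all_messages(q, code$k1)[best, ],
       index = best - 1L,
       codeword = cb[best, ],
       score = scores[best])
}

#' @export
print.outer_code <- function(x, ...) {
  cat("Outer code [GF(", x$field$q, "), n1 = ", x$n1, ", k1 = ", x$k1,
      "], d_H = ", x$d_H, " (", x$construction, "), ",
      nrow(x$codebook), " codewords\n", sep = "")
  invisible(x)
}
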