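#' Construct a barcode set from its components
#'
#' Assembles all `q1^k1` barcodes of a configuration by encoding every
#' message with the outer code, mapping outer symbols to inner words and
#' adding the watermark modulo 4. Used by the designer; end users normally
#' obtain sets via [search_code()].
#'
#' @param outer an `outer_code`.
#' @param inner an `inner_code` (cardinality = outer field order).
#' @param w watermark over Z4, length `n1 * n2`.
#' @return object of class `barcode_set`: list with `barcodes` (character),
#'   `indices` (0-based message indices), `config` (q1, k1, n1, n2, N),
#'   `watermark`, `inner`, `outer` and `filter_report` (NULL until
#'   filtered).
#' @export
generate_barcode_set <- function(outer, inner, w) {
  stopifnot(inherits(outer, "outer_code"), inherits(inner, "inner_code"))
  N <- outer$n1 * inner$n2
  if (length(w) != N) stop("watermark length != n1 * n2")
  bmat <- .assemble_matrix(outer$codebook, inner$words, as.integer(w))
  barcodes <- apply(matrix(c("A", "C", "G", "T")[bmat + 1L], nrow(bmat)), 2L,
                    paste, collapse = "")
  structure(list(barcodes = barcodes,
                 indices = 0:(ncol(bmat) - 1L),
                 config = list(q1 = outer$field$q, k1 = outer$k1,
                               n1 = outer$n1, n2 = inner$n2, N = N),
                 watermark = as.integer(w),
                 inner = inner,
                 outer = outer,
                 filter_report = NULL),
            class = "barcode_set")
}

# codebook (M x n1), words (q1 x n2), w (length N) -> N x M barcode matrix
.assemble_matrix <- function(codebook, words, w) {
  tW <- t(words)                                   # n2 x q1
  Sm <- matrix(tW[, t(codebook) + 1L], nrow = length(w))
  (Sm + w) %% 4L
}

#' Concatenated code rate
#'
#' `R = R1 * R2 = k1 * log2(q1) / (n1 * n2 * log2(4))`, the information
#' content of the `q1^k1` messages relative to the `4^N` possible DNA words
#' of barcode length `N = n1 * n2`.
#'
#' @param q1,k1,n1,n2 code configuration.
#' @return numeric rate in (0, 1).
#' @examples
#' code_rate(7, 2, 3, 8)   # 0.117
#' @export
code_rate <- function(q1, k1, n1, n2) {
  k1 * log2(q1) / (n1 * n2 * 2)
}

#' Enumerate admissible code configurations
#'
#' All `(q1, k1, n1, n2)` with `q1` in \{2,3,4,5,7,8,9\}, `n1` in 3..6,
#' `n2` in 4..8, barcode length `N = n1 * n2` in \[12, 25\], codebook size
#' `48 < q1^k1 < 1000` with `k1 < n1`, an achievable inner density below
#' 0.3, and a constructible outer code. Ordering is lexicographic in
#' `(q1, k1, n1, n2)`.
#'
#' @return data.frame with columns `q1, k1, n1, n2, N, size, R, d_H`.
#' @export
enumerate_configs <- function() {
  rows <- list()
  oc_cache <- new.env(parent = emptyenv())
  for (q1 in c(2L, 3L, 4L, 5L, 7L, 8L, 9L)) {
    for (k1 in 1:5) {
      size <- q1^k1
      if (size <= 48 || size >= 1000) next
      for (n1 in 3:6) {
        if (k1 >= n1) next
        key <- paste(q1, n1, k1, sep = "|")
        if (is.null(oc_cache[[key]])) {
          oc_cache[[key]] <- tryCatch(build_outer_code(q1, n1, k1),
                                      error = function(e) NA)
        }
        oc <- oc_cache[[key]]
        if (!inherits(oc, "outer_code")) next
        for (n2 in 4:8) {
          N <- n1 * n2
          if (N < 12L || N > 25L) next
          dmin <- min_inner_density(q1, n2)
          if (is.na(dmin) || dmin >= 0.3) next
          rows[[length(rows) + 1L]] <-
            data.frame(q1 = q1, k1 = k1, n1 = n1, n2 = n2, N = N,
                       size = size, R = code_rate(q1, k1, n1, n2),
                       d_H = oc$d_H)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Randomized watermark / inner-code search
#'
#' For each trial, samples a sparse inner code and a uniform random
#' watermark, assembles all `q1^k1` barcodes and applies the sequence
#' filters. The trial maximizing the survivor count is kept; ties are
#' broken by the larger mean edit distance among survivors, then by the
#' earlier trial (when more than 1000 trials tie at the maximum, the
#' earliest 1000 enter the edit-distance comparison). Deterministic for a
#' fixed `seed`.
#'
#' The per-trial assembly and filtering run in compiled code drawing from
#' R's RNG stream; a counting pass over all trials is followed by a replay
#' pass that re-materializes only the tying trials.
#'
#' @param q1,k1,n1,n2 code configuration (see [enumerate_configs()]).
#' @param trials number of random trials (>= 1).
#' @param seed optional integer seed (applied via [set.seed()]); if `NULL`
#'   the current RNG stream is used.
#' @param density_bound inner-code density bound (default 0.3).
#' @return object of class `c("designed_code", "barcode_set")`: the
#'   filtered best barcode set, plus provenance fields `search` (list with
#'   `trials`, `seed`, `best_trial`, `survivors`, `mean_edit`) and `status`
#'   (`"ok"`, or `"failed"` when no trial had survivors, in which case the
#'   set is empty).
#' @export
search_code <- function(q1, k1, n1, n2, trials = 1e5, seed = NULL,
                        density_bound = 0.3) {
  stopifnot(trials >= 1)
  trials <- as.integer(trials)
  if (!is.null(seed)) set.seed(seed)
  if (!exists(".Random.seed", globalenv())) stats::runif(1L)
  outer <- build_outer_code(q1, n1, k1)
  q1 <- outer$field$q
  n2 <- as.integer(n2)
  N <- n1 * n2
  dmin <- min_inner_density(q1, n2)
  if (is.na(dmin) || dmin >= density_bound) {
    stop("no inner code with density < ", density_bound, " for (q1, n2) = (",
         q1, ", ", n2, ")")
  }
  pool1 <- .weight1_pool(n2)
  pool2 <- .weight2_pool(n2)
  tcb <- t(outer$codebook)               # n1 x M, elements 0..q1-1

  state0 <- get(".Random.seed", envir = globalenv())
  counts <- .design_search_counts(tcb, pool1, pool2, q1, n2, trials)
  state_after <- get(".Random.seed", envir = globalenv())

  mx <- max(counts)
  ties <- which(counts == mx)
  if (length(ties) > 1000L) ties <- ties[seq_len(1000L)]
  assign(".Random.seed", state0, envir = globalenv())
  mats <- .design_search_materialize(tcb, pool1, pool2, q1, n2, trials,
                                     as.integer(ties))
  assign(".Random.seed", state_after, envir = globalenv())

  survivors_dE <- function(mat) {
    bmat <- .assemble_matrix(outer$codebook, mat$words, mat$w)
    pass <- .filter_matrix(bmat)$pass
    if (sum(pass) < 2L) return(0)
    s <- apply(matrix(c("A", "C", "G", "T")[bmat[, pass, drop = FALSE] + 1L], N),
               2L, paste, collapse = "")
    d <- utils::adist(s)
    mean(d[lower.tri(d)])
  }
  if (length(ties) > 1L && mx > 1L) {
    dEs <- vapply(mats, survivors_dE, numeric(1))
    win <- which.max(dEs)                # first maximum = earliest trial
    best_dE <- dEs[win]
  } else {
    win <- 1L
    best_dE <- NA_real_
  }
  best_trial <- ties[win]
  mat <- mats[[win]]

  inner <- new_inner_code(mat$words)
  full <- generate_barcode_set(outer, inner, mat$w)
  flt <- filter_set(full)
  out <- flt$set
  if (is.na(best_dE) && mx > 1L) best_dE <- distance_stats(out)$mean
  out$search <- list(trials = trials, seed = seed, best_trial = best_trial,
                     survivors = as.integer(mx),
                     mean_edit = if (mx > 1L) best_dE else NA_real_)
  out$status <- if (mx > 0L) "ok" else "failed"
  class(out) <- c("designed_code", "barcode_set")
  out
}

#' @export
print.barcode_set <- function(x, ...) {
  cfg <- x$config
  cat("Barcode set ", cfg$q1, "|", cfg$k1, "|", cfg$n1, "|", cfg$n2,
      " (N = ", cfg$N, "): ", length(x$barcodes), " barcodes\n", sep = "")
  if (inherits(x, "designed_code")) {
    cat("  search: ", x$search$trials, " trials, best trial ",
        x$search$best_trial, ", survivors ", x$search$survivors,
        if (!is.na(x$search$mean_edit))
          paste0(", mean edit distance ", round(x$search$mean_edit, 2)) else "",
        "\n", sep = "")
  }
  if (!is.null(x$filter_report)) print(x$filter_report)
  invisible(x)
}
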