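# Independent oracles used across the suite.

# Plain recursive (memoized) Levenshtein distance, independent of
# utils::adist.
levenshtein_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j else if (j == 0L) i else {
      min(rec(i - 1L, j) + 1L,
          rec(i, j - 1L) + 1L,
          rec(i - 1L, j - 1L) + (av[i] != bv[j]))
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(n, m)
}

# Brute-force path enumeration over all insertion/deletion/substitution
# event sequences: sums emission products over every composition of the
# read length into per-symbol observable lengths 0..I+1, weighted by the
# boundary priors. Per-position emission matrices Ms allow mixing the
# effective (watermark) matrix with the plain substitution matrix.
oracle_total <- function(r_int, labels, H, Ms, priorF, priorB, ys) {
  L <- length(r_int); N <- length(labels)
  rec <- function(i, pos) {
    if (i > N) {
      yi <- match(pos - N, ys)
      return(if (is.na(yi)) 0 else priorB[yi])
    }
    tot <- 0
    for (l in 0:(H$I + 1L)) {
      if (pos + l > L) next
      q <- if (l == 0L) emission_QE(0L, 0L, labels[i], Ms[[i]], H)
           else emission_QE(l, r_int[pos + l], labels[i], Ms[[i]], H)
      if (q > 0) tot <- tot + q * rec(i + 1L, pos + l)
    }
    tot
  }
  tot <- 0
  for (yi in seq_along(ys)) {
    if (priorF[yi] > 0 && ys[yi] >= 0 && ys[yi] <= L) {
      tot <- tot + priorF[yi] * rec(1L, ys[yi])
    }
  }
  tot
}

# Exhaustive field-axiom check for a galois_field (feasible for q <= 9).
check_field_axioms <- function(f) {
  q <- f$q
  el <- 0:(q - 1L)
  add <- f$add; mul <- f$mul
  expect_true(all(add == t(add)))               # commutativity
  expect_true(all(mul == t(mul)))
  expect_equal(add[, 1L], el)                   # identities
  expect_equal(mul[, 2L], el)
  expect_true(all(mul[1L, ] == 0L))             # absorbing zero
  for (a in el) for (b in el) for (cc in el) {
    expect_identical(add[add[a + 1, b + 1] + 1, cc + 1],
                     add[a + 1, add[b + 1, cc + 1] + 1])
    expect_identical(mul[mul[a + 1, b + 1] + 1, cc + 1],
                     mul[a + 1, mul[b + 1, cc + 1] + 1])
    expect_identical(mul[a + 1, add[b + 1, cc + 1] + 1],
                     add[mul[a + 1, b + 1] + 1, mul[a + 1, cc + 1] + 1])
  }
  for (a in el[-1L]) expect_identical(mul[a + 1, f$inv[a + 1] + 1], 1L)
}

# A small designed 8|3|6|4 set shared by decoder tests (deterministic).
shared_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- search_code(8, 3, 6, 4, trials = 200, seed = 5)
    cache
  }
})
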