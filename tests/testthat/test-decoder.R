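test_that("insertion weights and length distribution match their formulas", {
  expect_equal(insertion_weights(0, 2), c(1, 0, 0))
  a <- insertion_weights(0.05, 2)
  expect_equal(a[2], 0.05 / (1 - 0.05^2))
  expect_true(all(diff(a[-1]) <= 0))           # geometric decay beyond l' = 1
  expect_true(all(a >= 0))

  expect_equal(transition_distribution(0, 0, 2), c(0, 1, 0, 0))
  expect_equal(transition_distribution(0, 0.1, 2), c(0.1, 0.9, 0, 0))
  set.seed(20)
  for (rep in 1:10) {
    p_i <- stats::runif(1, 0, 0.3); p_d <- stats::runif(1, 0, 0.3)
    I <- sample(1:3, 1)
    expect_equal(sum(transition_distribution(p_i, p_d, I)), 1)
  }
})

test_that("emission probabilities obey the column-sum identity", {
  set.seed(21)
  for (rep in 1:8) {
    H <- hmm_params(S = uniform_substitution(stats::runif(1, 0, 0.4)),
                    p_i = stats::runif(1, 0, 0.25),
                    p_d = stats::runif(1, 0, 0.25), I = sample(1:3, 1))
    p <- transition_distribution(H$p_i, H$p_d, H$I)
    for (t in 0:3) {
      expect_equal(emission_QS(0L, 0L, t, H), p[1])
      for (l in seq_len(H$I + 1L)) {
        # 4^(l-1) insertion prefixes times the sum over the final symbol
        s <- 4^(l - 1) * sum(vapply(0:3, function(r)
          emission_QS(l, r, t, H), numeric(1)))
        expect_equal(s, p[l + 1])
      }
    }
    expect_error(emission_QS(H$I + 2L, 0L, 0L, H), "out of range")
  }
  # noiseless limit: Q^S(1, r, t) is the indicator of r == t
  H0 <- hmm_params(S = diag(4), p_i = 0, p_d = 0, I = 2)
  expect_equal(emission_QS(1L, 2L, 2L, H0), 1)
  expect_equal(emission_QS(1L, 1L, 2L, H0), 0)
  # pure substitution limit reads off the matrix entry
  He <- hmm_params(S = uniform_substitution(0.09), p_i = 0, p_d = 0, I = 2)
  expect_equal(emission_QS(1L, 1L, 2L, He), 0.03)
  # Q^E with E = S is Q^S
  expect_equal(emission_QE(1L, 1L, 2L, He$S, He), emission_QS(1L, 1L, 2L, He))
})

test_that("lattice terminal values equal brute-force path enumeration", {
  set.seed(22)
  for (case in 1:25) {
    N <- sample(2:4, 1); L <- sample(2:6, 1)
    labels <- sample(0:3, N, TRUE)
    r <- paste(c("A","C","G","T")[sample.int(4, L, TRUE)], collapse = "")
    H <- hmm_params(S = uniform_substitution(stats::runif(1, 0, 0.3)),
                    p_i = stats::runif(1, 0, 0.2),
                    p_d = stats::runif(1, 0, 0.2),
                    I = sample(1:2, 1), Delta = 10)
    Ms <- rep(list(H$S), N)
    # embedded: uniform start prior, flat end prior
    lat <- forward_backward(r, labels, H)
    ys <- lat$ys
    priorF <- as.numeric(ys >= 0) / (L + 1)
    priorB <- as.numeric(ys >= -N & ys <= L - N)
    o <- oracle_total(dna_map(r), labels, H, Ms, priorF, priorB, ys)
    expect_equal(exp(lat$loglik), o, tolerance = 1e-12)
    # non-embedded: point priors at drift 0 and |r| - N
    pf <- as.numeric(ys == 0); pb <- as.numeric(ys == L - N)
    o2 <- oracle_total(dna_map(r), labels, H, Ms, pf, pb, ys)
    lat2 <- forward_backward(r, labels, H, priorF = pf, priorB = pb)
    if (o2 == 0) {
      expect_true(lat2$loglik < log(1e-250) || !is.finite(lat2$loglik))
    } else {
      expect_equal(exp(lat2$loglik), o2, tolerance = 1e-12)
    }
  }
})

test_that("forward-backward total likelihood is invariant across cut points", {
  dc <- shared_design()
  H <- hmm_from_pmut(0.04, I = 2, Delta = 10)
  set.seed(23)
  batch <- make_batch(dc, channel_params(p_mut = 0.04), 10, defective_only = TRUE)
  for (i in 1:10) {
    lat <- watermark_lattice(batch$reads[[i]], dc, H)
    spread <- diff(range(lat$loglik_by_cut))
    expect_lt(spread, 1e-8 * max(1, abs(lat$loglik)))
  }
})

test_that("noiseless reads yield exact boundaries and certain posteriors", {
  dc <- shared_design()
  H <- hmm_from_pmut(0.003, I = 2, Delta = 10)
  b <- dc$barcodes[2]
  # no context: the barcode spans [0, N)
  lat <- watermark_lattice(b, dc, H)
  bd <- estimate_boundaries(lat)
  expect_identical(c(bd$start, bd$end), c(0L, 24L))
  post <- symbol_posteriors(lat, dc, H)
  expect_equal(rowSums(post), rep(1, 6))
  d_true <- encode_outer(dc$outer,
                         wmdemux:::.all_messages(8, 3)[dc$indices[2] + 1L, ])
  expect_identical(max.col(post) - 1L, d_true)
  # a single deletion inside the barcode shifts the end boundary by one
  bdel <- paste0(substr(b, 1, 9), substr(b, 11, 24))
  bdd <- estimate_boundaries(watermark_lattice(bdel, dc, H))
  expect_identical(c(bdd$start, bdd$end), c(0L, 23L))
})

test_that("block likelihood ratios match a mixed-emission path oracle", {
  # tiny 3-block code (N = 6) so the full-read enumeration stays feasible
  oc <- build_outer_code(4, 3, 2)           # RS over GF(4), n1 = 3
  set.seed(24)
  ic <- sample_inner_code(4, 2, density_bound = 0.6)
  w <- random_watermark(6)
  set <- generate_barcode_set(oc, ic, w)
  H <- hmm_params(S = uniform_substitution(0.1), p_i = 0.05, p_d = 0.05,
                  I = 2, Delta = 10)
  E <- effective_substitution(H$S, ic)
  r <- set$barcodes[7]
  lat <- watermark_lattice(r, set, H)
  post <- symbol_posteriors(lat, set, H)
  ys <- lat$ys
  priorF <- as.numeric(ys >= 0) / (nchar(r) + 1)
  priorB <- as.numeric(ys >= -6 & ys <= nchar(r) - 6)
  for (j in 1:3) {
    u <- (j - 1L) * 2L + 1L
    liks <- vapply(seq_len(4), function(sidx) {
      Ms <- rep(list(E), 6)
      labels <- w
      labels[u:(u + 1L)] <- (w[u:(u + 1L)] + ic$words[sidx, ]) %% 4L
      Ms[[u]] <- H$S
      Ms[[u + 1L]] <- H$S
      oracle_total(dna_map(r), labels, H, Ms, priorF, priorB, ys)
    }, numeric(1))
    expect_equal(post[j, ], liks / sum(liks), tolerance = 1e-10)
  }
})

test_that("optimal decoding reproduces closed forms in the substitution limit", {
  dc <- shared_design()
  N <- 24L
  # exact read, error-free model: likelihood 1
  H0 <- hmm_params(S = diag(4), p_i = 0, p_d = 0, I = 2, Delta = 10)
  sub <- dc
  sub$barcodes <- dc$barcodes[1:8]
  sub$indices <- dc$indices[1:8]
  od0 <- optimal_decode(sub$barcodes[3], sub, H0, embedded = FALSE)
  expect_equal(od0$loglik, 0)
  expect_identical(od0$index, sub$indices[3])
  # one substitution under a symmetric matrix: (1 - e)^(N-1) * e / 3
  e <- 0.12
  He <- hmm_params(S = uniform_substitution(e), p_i = 0, p_d = 0, I = 2)
  v <- dna_map(sub$barcodes[3])
  v[10] <- (v[10] + 1L) %% 4L
  od1 <- optimal_decode(dna_unmap(v), sub, He, embedded = FALSE)
  lik <- exp(od1$logliks[3])
  expect_equal(lik, (1 - e)^(N - 1) * e / 3, tolerance = 1e-10)
})

test_that("error-free embedded reads decode to the truth in both modes", {
  dc <- shared_design()
  H <- hmm_from_pmut(0.003, I = 2, Delta = 10)
  set.seed(25)
  batch <- make_batch(dc, channel_params(p_mut = 0), 5)
  for (i in 1:5) {
    sw <- decode(batch$reads[[i]], dc, H, "symbolwise")
    expect_identical(sw$index, batch$truth$index[i])
    expect_identical(sw$start, batch$truth$delta[i])
    expect_identical(sw$end, batch$truth$delta[i] + 24L)
  }
  # optimal mode on a reduced set (exhaustive per-barcode forward passes)
  sub <- dc
  sub$barcodes <- dc$barcodes[1:25]
  sub$indices <- dc$indices[1:25]
  set.seed(26)
  batch2 <- make_batch(sub, channel_params(p_mut = 0), 3)
  for (i in 1:3) {
    op <- decode(batch2$reads[[i]], sub, H, "optimal")
    expect_identical(op$index, batch2$truth$index[i])
  }
})

test_that("symbol-wise and optimal decoding agree on lightly corrupted reads", {
  dc <- shared_design()
  sub <- dc
  keep <- seq_len(40)
  sub$barcodes <- dc$barcodes[keep]
  sub$indices <- dc$indices[keep]
  H <- hmm_from_pmut(0.01, I = 2, Delta = 10)
  set.seed(27)
  batch <- make_batch(sub, channel_params(p_mut = 0.01), 20, defective_only = TRUE)
  agree <- 0L
  for (i in seq_len(20)) {
    sw <- decode(batch$reads[[i]], sub, H, "symbolwise")
    op <- optimal_decode(batch$reads[[i]], sub, H)
    agree <- agree + (sw$index == op$index)
  }
  expect_gte(agree, 19L)                       # >= 95% agreement
})

test_that("ambiguity codes act as uniform wildcards, not errors", {
  dc <- shared_design()
  H <- hmm_from_pmut(0.01, I = 2, Delta = 10)
  b <- dc$barcodes[4]
  rN <- paste0(substr(b, 1, 11), "N", substr(b, 13, 24))
  res <- decode(rN, dc, H, "symbolwise")
  expect_identical(res$index, dc$indices[4])
})

test_that("batch demultiplexing flags undecodable reads instead of failing", {
  dc <- shared_design()
  H <- hmm_from_pmut(0.01, I = 2, Delta = 10)
  reads <- c(good = dc$barcodes[1], bad = "")
  asg <- demux_reads(reads, dc, H)
  expect_identical(asg$index[1], dc$indices[1])
  expect_true(is.na(asg$index[2]))
  expect_identical(asg$read_id, c("good", "bad"))
})
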