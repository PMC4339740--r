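test_that("embedding places the barcode at the drawn offset", {
  b <- "ACGTTGCA"
  p0 <- channel_params(p_mut = 0.1, mu_l = 0, sigma_l = 0)
  emb0 <- embed_barcode(b, p0)
  expect_identical(emb0$t, b)
  expect_identical(emb0$delta, 0L)
  set.seed(14)
  p <- channel_params(p_mut = 0.1)             # defaults mu_l = 50, sigma_l = 5
  lens <- replicate(300, {
    e <- embed_barcode(b, p)
    expect_identical(substr(e$t, e$delta + 1, e$delta + nchar(b)), b)
    nchar(e$t)
  })
  # mean length N + 2 * mu_l, within 4 standard errors of the mean
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - (nchar(b) + 100)), 4 * se + 1)
})

test_that("the error-free channel is the identity and logs only C events", {
  p <- channel_params(p_mut = 0)
  tx <- transmit("ACGTTGCAACGT", p)
  expect_identical(tx$r, "ACGTTGCAACGT")
  expect_true(all(tx$events$type == "C"))
  expect_identical(nrow(tx$events), 12L)
})

test_that("event logs replay to the emitted read exactly", {
  set.seed(15)
  for (rep in 1:20) {
    t <- paste(c("A","C","G","T")[sample.int(4, 60, TRUE)], collapse = "")
    p <- if (rep %% 2 == 0) channel_params(p_mut = stats::runif(1, 0.05, 0.5)) else
      channel_params(S = uniform_substitution(stats::runif(1, 0, 0.3)),
                     p_i = stats::runif(1, 0, 0.2), p_d = stats::runif(1, 0, 0.2))
    tx <- transmit(t, p)
    expect_identical(replay_events(tx$events), tx$r)
    # one terminal event (C/S/D) per transmit symbol
    expect_identical(sum(tx$events$type != "I"), 60L)
  }
})

test_that("insertions and deletions balance in expectation (mode pmut)", {
  set.seed(16)
  p <- channel_params(p_mut = 0.3)
  L <- 50L
  t <- paste(rep("ACGT", 13), collapse = "")
  t <- substr(t, 1, L)
  lens <- replicate(3000, nchar(transmit(t, p)$r))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - L), 3 * se)
})

test_that("a heavily deleting matrix channel shortens reads", {
  set.seed(17)
  p <- channel_params(S = diag(4), p_i = 0, p_d = 0.9)
  lens <- replicate(50, nchar(transmit("ACGTACGTACGTACGTACGT", p)$r))
  expect_lt(mean(lens), 6)
  # no insertions possible: every read is a subsequence-length
  expect_true(all(lens <= 20))
})

test_that("defect probability follows 1 - (1 - p)^N", {
  expect_equal(pr_defective(0, 24), 0)
  expect_equal(pr_defective(1, 24), 1)
  expect_equal(pr_defective(0.1, 2), 0.19)
})

test_that("batches carry consistent ground truth and honor conditioning", {
  dc <- shared_design()
  p <- channel_params(p_mut = 0.05)
  empty <- make_batch(dc, p, 0)
  expect_identical(length(empty$reads), 0L)
  set.seed(18)
  batch <- make_batch(dc, p, 40, defective_only = TRUE)
  expect_true(all(batch$truth$defective))
  N <- dc$config$N
  for (i in 1:40) {
    ev <- batch$events[[i]]
    span <- (batch$truth$delta[i] + 1):(batch$truth$delta[i] + N)
    expect_true(any(ev$type != "C" & ev$pos %in% span))
    expect_identical(replay_events(ev), unname(batch$reads[i]))
    expect_identical(batch$truth$r_len[i], nchar(batch$reads[[i]]))
  }
  expect_true(all(batch$truth$index %in% dc$indices))
  expect_error(make_batch(dc, channel_params(p_mut = 0), 5, defective_only = TRUE),
               "conditioning impossible")
})

test_that("barcodes are drawn uniformly from the set", {
  dc <- shared_design()
  sub <- dc
  sub$barcodes <- dc$barcodes[1:4]
  sub$indices <- dc$indices[1:4]
  set.seed(19)
  batch <- make_batch(sub, channel_params(p_mut = 0.01, mu_l = 0, sigma_l = 0), 4000)
  counts <- table(factor(batch$truth$index, levels = sub$indices))
  chi <- sum((counts - 1000)^2 / 1000)
  # chi-square with 3 df: 99.9% quantile ~ 16.27
  expect_lt(chi, stats::qchisq(0.999, 3))
})
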