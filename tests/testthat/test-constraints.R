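test_that("constraint rules match their definitions on constructed cases", {
  # "ACGTACGTACGT" is its own reverse complement (checked explicitly here)
  x <- "ACGTACGTACGT"
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
  expect_identical(rc, x)
  res <- passes_constraints(x)
  expect_false(res$pass)
  expect_identical(res$violated, "self_complement")
  res2 <- passes_constraints("AAATTT")
  expect_false(res2$pass)
  # fails GC and homopolymer, and is also its own reverse complement
  expect_setequal(res2$violated, c("gc", "homopolymer", "self_complement"))
  res3 <- passes_constraints("AAAGTC")
  expect_setequal(res3$violated, c("gc", "homopolymer"))
  expect_true(passes_constraints("ACGTTGCATGA")$pass)
  # GC bounds are inclusive: 2/5 and 3/5 pass
  expect_false("gc" %in% passes_constraints("ACGTA")$violated)  # 2/5
  expect_false("gc" %in% passes_constraints("ACGCA")$violated)  # 3/5
  expect_true("gc" %in% passes_constraints("ACGCC")$violated)   # 4/5
  expect_error(passes_constraints("ACGN"), "non-ACGT")
})

test_that("odd-length barcodes can never be perfect reverse-complement palindromes", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(c(5L, 7L, 9L, 11L), 1)
    x <- paste(c("A", "C", "G", "T")[sample.int(4, n, TRUE)], collapse = "")
    expect_false("self_complement" %in% passes_constraints(x)$violated)
  }
})

test_that("edit distance agrees with a recursive oracle and is bounded by Hamming", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  expect_identical(edit_distance("ACGT", "AGT"), 1L)
  expect_identical(edit_distance("ACGT", ""), 4L)
  # all pairs of short strings over {A, C}
  pool <- c("", "A", "C", "AC", "CA", "AAC", "CCA")
  for (a in pool) for (b in pool) {
    expect_identical(edit_distance(a, b), levenshtein_oracle(a, b))
  }
  set.seed(8)
  for (rep in 1:30) {
    a <- paste(c("A","C","G","T")[sample.int(4, sample(1:6, 1), TRUE)], collapse = "")
    b <- paste(c("A","C","G","T")[sample.int(4, sample(1:6, 1), TRUE)], collapse = "")
    expect_identical(edit_distance(a, b), levenshtein_oracle(a, b))
    expect_identical(edit_distance(a, b), edit_distance(b, a))
  }
  for (rep in 1:20) {
    a <- sample.int(4, 10, TRUE); b <- sample.int(4, 10, TRUE)
    sa <- paste(c("A","C","G","T")[a], collapse = "")
    sb <- paste(c("A","C","G","T")[b], collapse = "")
    expect_lte(edit_distance(sa, sb), sum(a != b))
  }
})

test_that("distance statistics use ordered-pair normalization", {
  two <- c("AAACA", "GGTGG")
  st <- distance_stats(two)
  d <- levenshtein_oracle(two[1], two[2])
  expect_equal(st$mean, d)
  expect_identical(names(st$distribution), as.character(d))
  expect_equal(unname(st$distribution), 1)
  set.seed(12)
  bs <- replicate(6, paste(c("A","C","G","T")[sample.int(4, 8, TRUE)], collapse = ""))
  st2 <- distance_stats(bs)
  expect_equal(sum(st2$distribution), 1)
  # independent double loop over ordered pairs
  tot <- 0; cnt <- 0
  for (i in seq_along(bs)) for (j in seq_along(bs)) if (i != j) {
    tot <- tot + levenshtein_oracle(bs[i], bs[j]); cnt <- cnt + 1
  }
  expect_equal(st2$mean, tot / cnt)
  expect_error(distance_stats("ACGT"), "at least 2")
})

test_that("filtering keeps exactly the passing barcodes with their indices", {
  oc <- build_outer_code(7, 3, 2)
  set.seed(2)
  ic <- sample_inner_code(7, 4)
  set <- generate_barcode_set(oc, ic, random_watermark(12))
  out <- filter_set(set)
  expect_identical(out$report$surviving + out$report$excluded, out$report$input)
  expect_identical(length(out$set$barcodes), out$report$surviving)
  for (k in seq_along(out$set$barcodes)) {
    expect_true(passes_constraints(out$set$barcodes[k])$pass)
  }
  # survivors keep their original message index
  expect_identical(out$set$barcodes,
                   set$barcodes[match(out$set$indices, set$indices)])
  # a set that passes entirely is unchanged
  keep <- set
  keep$barcodes <- out$set$barcodes
  keep$indices <- out$set$indices
  again <- filter_set(keep)
  expect_identical(again$set$barcodes, keep$barcodes)
  expect_identical(again$report$excluded, 0L)
})
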