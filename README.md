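# wmdemux — watermark DNA barcodes robust to insertions and deletions

`wmdemux` designs and demultiplexes synchronizing DNA barcodes for
multiplexed sequencing on error channels where insertions and deletions
matter as much as substitutions. Classical Hamming-distance barcodes lose
the positional correspondence between sent and received symbols after a
single indel, and when the barcode is embedded in unknown flanking
sequence even its boundaries are uncertain. Watermark codes solve both
problems structurally: every barcode is a small sparse perturbation of a
single shared *watermark* sequence, so one hidden Markov model over
insertion/deletion *drift* states can re-synchronize, locate and decode
the barcode without any primer, marker or known context.

## The construction

A configuration `q1|k1|n1|n2` concatenates

* an outer linear code `C1[GF(q1), n1, k1]` (Reed–Solomon/MDS wherever
  `n1 ≤ q1 + 1`, so `d_H = n1 − k1 + 1`), encoding `q1^k1` messages;
* an inner map `C2` from each outer symbol to one of `q1` sparse nonzero
  words of length `n2` over Z4 (mean density < 0.3);
* a watermark `w ∈ Z4^N`, `N = n1·n2`: the barcode is `b = s ⊕ w (mod 4)`
  under A=0, C=1, G=2, T=3, where `s` concatenates the inner words.

The rate is `R = k1·log2(q1)/(n1·n2·log2 4)` — e.g. 0.117 for `7|2|3|8`,
0.188 for `8|3|6|4`, 0.281 for `8|3|4|4`. `search_code()` optimizes the
watermark/inner-code pair by randomized search under biological filters
(GC content in [0.40, 0.60], homopolymers ≤ 2, no reverse-complement
palindromes), keeping the trial with the most surviving barcodes (ties:
larger mean edit distance). Decoding runs a forward–backward pass of the
drift HMM against the watermark to find the barcode span, computes
symbol-wise posteriors of the outer symbols per inner block, and finishes
with soft maximum-likelihood decoding of the outer code; an exact
(exhaustive) maximum-likelihood decoder is included as a reference. See
`vignettes/watermark-barcodes.Rmd` for the model details.

## Worked example

Design a barcode set on the `8|3|6|4` configuration, simulate corrupted
reads at a 4% per-symbol error rate, and demultiplex them:

```r
library(wmdemux)

dc <- search_code(8, 3, 6, 4, trials = 2e4, seed = 42)
dc
#> Barcode set 8|3|6|4 (N = 24): 359 barcodes
#>   search: 20000 trials, best trial 3173, survivors 359, mean edit distance 9.64
#> Constraint filter: 359/512 barcodes kept (gc: 84, homopolymer: 92, self-complement: 0 violations)

set.seed(42)
batch <- make_batch(dc, channel_params(p_mut = 0.04), 200, defective_only = TRUE)
H <- hmm_from_pmut(0.04, I = 2, Delta = 10)
asg <- demux_reads(batch$reads, dc, H)
sum(asg$index == batch$truth$index)
#> [1] 195
head(asg, 3)
#>      read_id index     loglik start end       mode
#> 1 read000001    66 -0.7398365    40  64 symbolwise
#> 2 read000002   458 -4.9751875    45  69 symbolwise
#> 3 read000003   211 -0.6024374    44  69 symbolwise
```

359 of the 512 possible barcodes survive the biological filters at this
small trial budget (a 10⁶-trial search retains > 400). Every read embeds
its barcode between ~50 random context symbols on each side and is forced
to carry at least one error event on the barcode (`defective_only`);
195/200 such reads are still assigned to the correct sample, and the
reported `start`/`end` columns recover the barcode span found by the
watermark synchronization. `evaluate_code()` turns this into decoding
error curves over a grid of error rates.

A command-line interface with subcommands `design`, `encode`, `simulate`,
`demux` and `evaluate` is provided in `inst/scripts/wmdemux`.

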