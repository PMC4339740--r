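---
title: "Watermark barcodes: model, design search and HMM demultiplexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Watermark barcodes: model, design search and HMM demultiplexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmdemux)
```

## The problem

Multiplexed sequencing tags every DNA fragment with a short synthetic
barcode; demultiplexing assigns each read back to its sample. Classical
barcode families optimize Hamming distance and correct substitutions, but
platforms with frequent insertions and deletions (pyrosequencing, SMRT,
nanopore-style channels) break the positional correspondence that Hamming
decoding relies on — and when the barcode sits inside unknown flanking
sequence, even its boundaries are uncertain. `wmdemux` implements a
*watermark* construction in which every barcode is a small, sparse
perturbation of one shared reference sequence, so a single hidden Markov
model can simultaneously re-synchronize against insertions/deletions,
locate the barcode in an arbitrary context, and decode it.

## The code construction

A configuration is written `q1|k1|n1|n2`:

* **Outer code** `C1[GF(q1), n1, k1]`: a linear block code over the Galois
  field of order `q1 ∈ {2,3,4,5,7,8,9}`. Messages `c` (length `k1`) are
  encoded as `d = c·G` with a systematic generator matrix. Whenever
  `n1 ≤ q1 + 1` the package constructs an (extended) Reed–Solomon code,
  which is MDS: `d_H = n1 − k1 + 1`. This reproduces the distance levels
  2, 3, 4 at `n1 = 4, 5, 6` for the GF(8), `k1 = 3` family. The few
  admissible configurations beyond RS length are served from a registry of
  fixed generator matrices. Two of these are double-parity codes with
  `d_H = 2` because `d_H = 3` is *provably unattainable* at `[6,4]` over
  GF(3) and GF(4): a systematic form would need four pairwise
  non-proportional rows of all-nonzero pairs, but only two (GF(3)) or
  three (GF(4)) projective classes of such pairs exist. Every constructed
  code re-verifies its distance by exhaustive weight enumeration (the
  admissibility rule `48 < q1^k1 < 1000` keeps this trivial).
* **Inner code** `C2`: each outer symbol maps to one of `q1` distinct
  nonzero words of length `n2` over Z4. Sparsity is essential — the
  watermark must "shine through" — so sampling draws from the weight-1
  pool first (topping up from weight-2 only when `q1 > 3·n2`) and the mean
  density must stay below 0.3.
* **Watermark** `w`: an arbitrary Z4 sequence of length `N = n1·n2`. A
  barcode is `b = s ⊕ w (mod 4)` where `s` concatenates the inner words;
  DNA is mapped as A=0, C=1, G=2, T=3 (any bijection is
  information-equivalent; this one is fixed and recorded in all outputs).

The concatenated rate is `R = R1·R2 = k1·log2(q1) / (n1·n2·log2 4)`: the
information content of the `q1^k1` messages against the `4^N` DNA words of
the full barcode length. For example `log2(7²)/log2(4²⁴) = 0.117` for
`7|2|3|8`, and 0.188 / 0.281 for `8|3|6|4` / `8|3|4|4`.

## Design search under biological constraints

`search_code()` repeats: draw an inner code and a uniform watermark,
assemble all `q1^k1` barcodes, and count how many pass three filters —
GC fraction within [0.40, 0.60] (bounds inclusive; the verbal rule "not
below 40% and above 60%" is boundary-ambiguous, and inclusion only affects
exact-boundary counts), no homopolymer longer than 2, and no perfect
reverse-complement palindromes (impossible at odd `N`). The best trial by
survivor count wins; ties prefer the larger mean edit distance among
survivors, then the earlier trial (at most the earliest 1000 tying trials
enter the edit-distance comparison, a bound that keeps the tie-break
affordable; in practice ties at the running maximum are rare for large
sets). The trial loop runs in compiled code against R's RNG, so results
are reproducible from a single seed; a counting pass is followed by a
replay pass that re-materializes only the tying trials. One million trials
of the 8|3|6|4 configuration (512 barcodes each) take on the order of two
minutes, and survivor counts saturate slowly with the budget (typically
~410–420 of 512 at 10⁶ versus ~400 at 10⁵; further gains towards 10⁷ are
only logarithmic).

## Channel model

The simulator treats each transmitted symbol as queued in a memoryless
state machine. The evaluation channel uses a single per-symbol error
probability `p_mut`: a round is correct with probability `1 − p_mut`, or a
substitution (always to a different base, uniformly), insertion (emit a
uniform random base, symbol stays queued), or deletion, each with
probability `p_mut/3`. Insertions repeat, so read lengths balance in
expectation. A matrix mode (`S`, `p_i`, `p_d`) exposes the general
parameterization. Barcodes are embedded between two random contexts whose
lengths are nearest-non-negative-integer normal draws with mean `mu_l = 50`
and spread `sigma_l = 5`; the spread is interpreted as a standard
deviation (both parameters are configurable). Ground
truth records the true index, offset and a per-symbol event log that
replays to the read exactly.

## Decoding

The decoder HMM tracks the *drift* (insertions minus deletions) before
each transmitted symbol. Observables per symbol are up to `I` leading
insertions followed by the (possibly substituted) symbol or its deletion.
The insertion weights `alpha(l') = p_i^l'/(1 − p_i^I)` and the emission
form `Q(l, r, t) = (alpha(l)/4^l)·p_d + (alpha(l−1)/4^(l−1))·p_t·S(r, t)`
follow the printed model, with one repair: evaluated on support
`l' = 0..I` the raw lengths distribution does not sum to one, so `p(l)`
and the emission constants are renormalized by a common factor, restoring
a proper HMM while keeping the printed formulas recognizable
(`transition_distribution()` documents this).

Three passes share one scaled forward/backward engine:

1. **Boundary pass**: the read against the watermark, with the *effective*
   substitution matrix `E = S·S'`, where `S'(b,w) = P((b−w) mod 4)` is the
   pooled symbol prior of the inner code (iid working assumption;
   per-position priors are out of scope). Start/end priors are uniform
   (`F_1(y) = 1/(|r|+1)` on `0 ≤ y ≤ |r|`; `B_N(y) = 1` on
   `−N ≤ y ≤ |r|−N`); the likeliest drifts at the two ends give the
   barcode span.
2. **Symbol-wise pass**: for each block `j` and inner word `s`, the block
   likelihood is `Σ_{y,z} F_u(y)·π_u(y,z,s)·B_v(z)` with `π` a truncated
   forward metric using plain `Q^S` emissions on labels `w ⊕ s`. By
   linearity of the recursion the sum over start drifts is computed as a
   single truncated pass initialized with the row `F_u`, pruned to drifts
   within `Delta` of the likeliest block-start drift. Normalizing over the
   `q1` words gives the posterior of each outer symbol.
3. **Outer soft-ML**: exhaustive argmax of `Σ_j log P(d_j)` over the
   codebook (≤ 1000 words), restricted to the message indices that
   survived filtering, with ties towards the smallest index.

An optimal reference decoder maximizes the full read likelihood over all
barcodes (`optimal_decode()`); it is exact but `q1^k1` times more
expensive and serves as the benchmark in the test suite. Decoding cost per
read scales as `O(|t|·|r|·I + q1·N·Delta·I + q1^k1)`.

## Numerical choices

* All lattice storage is scaled per step with cumulative log-scale
  factors (barcodes of length 24 inside ~150 nt reads would underflow
  doubles otherwise). The forward/backward product is invariant across cut
  points to < 1e−8 relative, asserted on every tested read.
* Read positions referenced outside the read contribute zero; reads with
  `N`/ambiguity codes treat those positions as uniform-emission wildcards
  (the emission marginalizes over the four bases).
* Ties break towards the smaller drift/index everywhere.
* Drift states span `−N .. |r|` in the boundary pass (the uniform priors
  support everything, so the `Delta` window prunes only the symbol-wise
  pass, anchored at the estimated block-start drift); `Delta` defaults to
  10, inside the suggested 5..20 range.
* The truncated forward metric `π` restarts at a point mass on the start
  drift; the per-block evaluation is the linearity-combined version
  described above.

## What the synthetic data does and does not emulate

The generator reproduces the study conditions: uniform barcode draws,
normal context lengths (mean 50 per side, so ~100 context symbols per
read), the equal-split error channel over `p_mut ∈ [.01, .16]`, and
conditioning on *defective* reads (≥ 1 error event on the barcode) with
`Pr(def) = 1 − (1−p_mut)^N`, error-free reads being counted as correctly
decoded. It does not model context-dependent or homopolymer burst errors,
quality scores, platform-specific profiles, reverse-complement reads, or
reads lacking a barcode entirely (decoding is conditioned on presence).
Passing tests therefore demonstrate correctness of the construction and
decoder under the stated memoryless channel, not performance on any
particular instrument.

## Problem sizes used in the tests

The suite verifies field axioms exhaustively (≤ 9³ triples), outer
distances by full weight enumeration, lattice likelihoods against a
brute-force path-enumeration oracle on instances with `N ≤ 4`, `|r| ≤ 6`,
`I ≤ 2`, block posteriors against a mixed-emission oracle on an `N = 6`
toy code, perfect decoding and exact boundary recovery on 1000 error-free
embedded reads, and a monotone error curve over
`p_mut ∈ {.01, .04, .08, .16}` at 2000 defective reads per point. The
design-search acceptance runs 10⁶ trials; these sizes keep a full run in
the low minutes while leaving every statistical check several standard
errors of headroom.

## Known limitations

* Randomized designs are not expected to reproduce any particular barcode
  set across implementations or seeds; distances, rates, cardinalities
  and survivor counts are the reproducible quantities, not individual
  sequences.
* The enumeration of admissible configurations follows the documented
  rules only; the total count of candidate configurations depends on
  which outer codes one treats as constructible and is deliberately not
  asserted.
* The HMM truncates insertions at `I` per observable while the channel
  does not — a deliberate model/decoder mismatch inherited from the
  construction; at the evaluated error rates the effect is negligible.
* Presence/absence detection, channels with memory, and quality-aware
  decoding are out of scope.
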