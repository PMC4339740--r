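// Hot loop of the randomized watermark / inner-code search.
//
// Each trial draws an inner code (subset of the low-weight word pools) and
// a uniform watermark from R's RNG stream, assembles all barcodes of the
// configuration and counts how many pass the GC / homopolymer /
// self-complementarity filters. Two entry points share one per-trial draw
// discipline (take1 + take2 + N variates, always consumed), so that a
// counting pass and a later materialization pass replay identical trials
// from the same RNG state.
//
// A barcode is the block concatenation b_j = word(d_j) + w_block_j (mod 4),
// so for a fixed trial only q1 realizations exist per block. All filter
// information is therefore precomputed per (block, symbol): GC count, run
// structure (internal maximum, leading/trailing run), and a pairwise table
// of which block realizations are reverse-complementary to the mirror
// block. Each of the q1^k1 barcodes is then screened in O(n1).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int rint(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// partial Fisher-Yates: 'take' distinct values from 0..n-1 (consumes
// exactly 'take' variates)
static void draw_subset(int n, int take, std::vector<int> &scratch, int *out) {
  for (int i = 0; i < n; ++i) scratch[i] = i;
  for (int i = 0; i < take; ++i) {
    int j = i + rint(n - i);
    std::swap(scratch[i], scratch[j]);
    out[i] = scratch[i];
  }
}

struct BlockInfo {
  int gc;        // count of C/G symbols
  int maxrun;    // longest run strictly inside the block
  int lead_sym, lead_len, tail_sym, tail_len;
  bool selfpair; // block is its own reverse complement (for a middle block)
};

struct Searcher {
  int n1, n2, N, M, q1, take1, take2, pool1n, pool2n, gclo, gchi, half;
  bool odd;
  const IntegerMatrix tcb, pool1, pool2;
  std::vector<int> scratch, sel, words, w, blk, dbuf;
  std::vector<BlockInfo> info;          // n1 * q1
  std::vector<unsigned char> pair;      // half * q1 * q1

  Searcher(IntegerMatrix tcb_, IntegerMatrix pool1_, IntegerMatrix pool2_,
           int q1_, int n2_)
    : n1(tcb_.nrow()), n2(n2_), N(tcb_.nrow() * n2_), M(tcb_.ncol()), q1(q1_),
      take1(std::min(q1_, (int)pool1_.nrow())),
      take2(std::max(0, q1_ - (int)pool1_.nrow())),
      pool1n(pool1_.nrow()), pool2n(pool2_.nrow()),
      gclo(0), gchi(0), half(tcb_.nrow() / 2), odd(tcb_.nrow() % 2 == 1),
      tcb(tcb_), pool1(pool1_), pool2(pool2_),
      scratch(std::max(pool1n, std::max(pool2n, 1))), sel(q1_),
      words(q1_ * n2_), w(N), blk(tcb_.nrow() * q1_ * n2_), dbuf(tcb_.nrow()),
      info(tcb_.nrow() * q1_), pair(half * q1_ * q1_ + 1) {
    // GC fraction in [0.40, 0.60] inclusive: 2N <= 5*gc <= 3N
    gclo = (2 * N + 4) / 5;             // smallest gc with 5*gc >= 2N
    gchi = (3 * N) / 5;                 // largest gc with 5*gc <= 3N
  }

  // consume one trial's randomness and fill words + w
  void draw_trial() {
    draw_subset(pool1n, take1, scratch, sel.data());
    if (take2 > 0) draw_subset(pool2n, take2, scratch, sel.data() + take1);
    for (int k = 0; k < q1; ++k) {
      const IntegerMatrix &pool = (k < take1) ? pool1 : pool2;
      int row = sel[k];
      for (int p = 0; p < n2; ++p) words[k * n2 + p] = pool(row, p);
    }
    for (int i = 0; i < N; ++i) w[i] = rint(4);
  }

  void precompute() {
    for (int j = 0; j < n1; ++j) {
      for (int d = 0; d < q1; ++d) {
        int *b = &blk[(j * q1 + d) * n2];
        BlockInfo &bi = info[j * q1 + d];
        bi.gc = 0;
        int run = 1, maxrun = 1;
        for (int p = 0; p < n2; ++p) {
          b[p] = (words[d * n2 + p] + w[j * n2 + p]) & 3;
          if (b[p] == 1 || b[p] == 2) ++bi.gc;
          if (p > 0) {
            run = (b[p] == b[p - 1]) ? run + 1 : 1;
            if (run > maxrun) maxrun = run;
          }
        }
        bi.maxrun = maxrun;
        bi.lead_sym = b[0];
        bi.lead_len = 1;
        while (bi.lead_len < n2 && b[bi.lead_len] == b[0]) ++bi.lead_len;
        bi.tail_sym = b[n2 - 1];
        bi.tail_len = 1;
        while (bi.tail_len < n2 && b[n2 - 1 - bi.tail_len] == b[n2 - 1])
          ++bi.tail_len;
        if (odd && j == half) {
          bi.selfpair = true;
          for (int p = 0; p < n2; ++p)
            if (b[p] + b[n2 - 1 - p] != 3) { bi.selfpair = false; break; }
        }
      }
    }
    // pair[j][d1][d2]: block j realization d1 is the reverse complement of
    // mirror-block realization d2
    for (int j = 0; j < half; ++j) {
      int jj = n1 - 1 - j;
      for (int d1 = 0; d1 < q1; ++d1) {
        const int *b1 = &blk[(j * q1 + d1) * n2];
        for (int d2 = 0; d2 < q1; ++d2) {
          const int *b2 = &blk[(jj * q1 + d2) * n2];
          bool ok = true;
          for (int p = 0; p < n2; ++p)
            if (b1[p] + b2[n2 - 1 - p] != 3) { ok = false; break; }
          pair[(j * q1 + d1) * q1 + d2] = ok;
        }
      }
    }
  }

  int count_survivors() {
    precompute();
    int count = 0;
    for (int m = 0; m < M; ++m) {
      for (int j = 0; j < n1; ++j) dbuf[j] = tcb(j, m);
      int gc = 0;
      for (int j = 0; j < n1; ++j) gc += info[j * q1 + dbuf[j]].gc;
      if (gc < gclo || gc > gchi) continue;
      // homopolymer: merge per-block run summaries left to right
      bool ok = true;
      int ts = -1, tl = 0;
      for (int j = 0; j < n1 && ok; ++j) {
        const BlockInfo &bi = info[j * q1 + dbuf[j]];
        if (bi.maxrun > 2) { ok = false; break; }
        if (bi.lead_sym == ts) {
          if (tl + bi.lead_len > 2) { ok = false; break; }
          if (bi.lead_len == n2) { tl += n2; continue; }   // uniform block
        } else if (bi.lead_len == n2) {
          ts = bi.lead_sym; tl = n2;
          if (tl > 2) { ok = false; }
          continue;
        }
        ts = bi.tail_sym;
        tl = bi.tail_len;
      }
      if (!ok) continue;
      // self-complementarity: all mirror block pairs reverse-complementary
      bool selfc = true;
      for (int j = 0; j < half && selfc; ++j)
        selfc = pair[(j * q1 + dbuf[j]) * q1 + dbuf[n1 - 1 - j]];
      if (selfc && odd) selfc = info[half * q1 + dbuf[half]].selfpair;
      if (!selfc) ++count;
    }
    return count;
  }
};

// [[Rcpp::export(name = ".design_search_counts")]]
IntegerVector design_search_counts(IntegerMatrix tcb, IntegerMatrix pool1,
                                   IntegerMatrix pool2, int q1, int n2,
                                   int trials) {
  Searcher s(tcb, pool1, pool2, q1, n2);
  IntegerVector counts(trials);
  for (int t = 0; t < trials; ++t) {
    s.draw_trial();
    counts[t] = s.count_survivors();
  }
  return counts;
}

// [[Rcpp::export(name = ".design_search_materialize")]]
List design_search_materialize(IntegerMatrix tcb, IntegerMatrix pool1,
                               IntegerMatrix pool2, int q1, int n2,
                               int trials, IntegerVector wanted) {
  Searcher s(tcb, pool1, pool2, q1, n2);
  List out(wanted.size());
  int next = 0;
  for (int t = 0; t < trials && next < wanted.size(); ++t) {
    s.draw_trial();
    if (t + 1 == wanted[next]) {          // wanted is 1-based and sorted
      IntegerMatrix wm(q1, n2);
      for (int k = 0; k < q1; ++k)
        for (int p = 0; p < n2; ++p) wm(k, p) = s.words[k * n2 + p];
      out[next] = List::create(_["words"] = wm,
                               _["w"] = IntegerVector(s.w.begin(), s.w.end()));
      ++next;
    }
  }
  return out;
}
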