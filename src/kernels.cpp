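#include <Rcpp.h>
using namespace Rcpp;

// Shared low-level scanners. Sequences are pre-encoded in R as integer
// matrices (one row per sequence, one column per position) with
// A=1, C=2, G=3, T=4 and 0 for N / out-of-bounds padding.

// Additive window scores for every window start of every sequence.
// energy: w x 4 matrix (position x base); a 0-code contributes 0, so callers
// can pad sequences to let windows hang over the ends.
// [[Rcpp::export]]
NumericMatrix cpp_window_scores(const IntegerMatrix& codes,
                                const NumericMatrix& energy) {
  const int n = codes.nrow(), L = codes.ncol(), w = energy.nrow();
  const int K = L - w + 1;
  if (K < 1) stop("window wider than sequence");
  NumericMatrix out(n, K);
  for (int o = 0; o < K; ++o) {
    for (int p = 0; p < w; ++p) {
      const int col = o + p;
      for (int i = 0; i < n; ++i) {
        const int b = codes(i, col);
        if (b > 0) out(i, o) += energy(p, b - 1);
      }
    }
  }
  return out;
}

// Multinomial seed counting for PWM construction (one scan direction).
// allowed: 4 x w logical matrix of bases accepted by the IUPAC seed.
// Column c counts the bases of windows that match the seed at every
// position other than c with at most (level - 1) mismatches: at level 1
// only exact matches fill all columns and 1-mismatch windows contribute
// solely at their mismatched column; at level 2 a 1-mismatch window fills
// every column and 2-mismatch windows contribute at their two mismatched
// columns. N (code 0) never matches. Returns 4 x w counts plus the number
// of contributing windows (mismatches <= level).
// [[Rcpp::export]]
List cpp_seed_counts(const IntegerMatrix& codes,
                     const LogicalMatrix& allowed,
                     const int level) {
  const int n = codes.nrow(), L = codes.ncol(), w = allowed.ncol();
  const int K = L - w + 1;
  NumericMatrix counts(4, w);
  long long n_used = 0, n_exact = 0;
  if (K < 1)
    return List::create(_["counts"] = counts, _["n"] = 0.0, _["n_exact"] = 0.0);
  std::vector<int> win(w), mmpos(w);
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < K; ++o) {
      int mm = 0;
      for (int p = 0; p < w; ++p) {
        const int b = codes(i, o + p);
        win[p] = b;
        if (b == 0 || !allowed(b - 1, p)) {
          if (++mm > level) break;
          mmpos[mm - 1] = p;
        }
      }
      if (mm > level) continue;
      ++n_used;
      if (mm == 0) ++n_exact;
      if (mm < level) {
        for (int p = 0; p < w; ++p) counts(win[p] - 1, p) += 1.0;
      } else {
        for (int q = 0; q < mm; ++q) {
          const int p = mmpos[q];
          if (win[p] > 0) counts(win[p] - 1, p) += 1.0;
        }
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["n"] = (double)n_used,
                      _["n_exact"] = (double)n_exact);
}

// Count, per sequence, windows scoring >= threshold under an additive
// score matrix (position x base). Used for fast motif-hit counting.
// [[Rcpp::export]]
IntegerVector cpp_count_hits(const IntegerMatrix& codes,
                             const NumericMatrix& score,
                             const double threshold) {
  const int n = codes.nrow(), L = codes.ncol(), w = score.nrow();
  const int K = L - w + 1;
  IntegerVector out(n);
  if (K < 1) return out;
  for (int i = 0; i < n; ++i) {
    int hits = 0;
    for (int o = 0; o < K; ++o) {
      double s = 0.0;
      for (int p = 0; p < w; ++p) {
        const int b = codes(i, o + p);
        if (b > 0) s += score(p, b - 1);
      }
      if (s >= threshold) ++hits;
    }
    out[i] = hits;
  }
  return out;
}
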