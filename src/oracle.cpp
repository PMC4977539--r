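#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Exhaustive alignment oracle: no index, no hashing.  For every strand,
// every read offset q and every genome position p it tests the exact
// seed_length-mer match by direct character comparison and, on a match,
// rescans the diagonal outwards to find the best-scoring segment that
// contains the seed.  Quadratic in genome length x read length; used
// only to verify the seeded aligner on small instances.

static char oracle_comp(char c) {
  if (c == 'A') return 'T';
  if (c == 'C') return 'G';
  if (c == 'G') return 'C';
  if (c == 'T') return 'A';
  return 'N';
}

static bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
DataFrame cpp_oracle_align_batch(CharacterVector reads, std::string genome,
                                 int k, int seed_mismatches,
                                 int match, int mismatch,
                                 int min_score, bool both_strands) {
  const int Lg = (int)genome.size();
  const int n = reads.size();
  IntegerVector out_score(n, NA_INTEGER), out_start(n, NA_INTEGER),
    out_end(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int Lr = (int)fwd.size();
    std::string rev(Lr, 'N');
    for (int j = 0; j < Lr; ++j) rev[Lr - 1 - j] = oracle_comp(fwd[j]);

    bool found = false;
    int b_score = 0, b_start = 0, b_end = 0;
    char b_strand = '+';

    const int n_strands = both_strands ? 2 : 1;
    for (int si = 0; si < n_strands; ++si) {
      const char strand = (si == 0) ? '+' : '-';
      const std::string &s = (si == 0) ? fwd : rev;
      for (int q = 0; q + k <= Lr; ++q) {
        // a seed must be unambiguous
        bool clean = true;
        for (int t = 0; t < k; ++t)
          if (!is_acgt(s[q + t])) { clean = false; break; }
        if (!clean) continue;
        for (int p = 0; p + k <= Lg; ++p) {
          // seed window must have at most seed_mismatches mismatches
          int nmis = 0;
          for (int t = 0; t < k; ++t)
            if (genome[p + t] != s[q + t] && ++nmis > seed_mismatches)
              break;
          if (nmis > seed_mismatches) continue;
          const int seed_score = (k - nmis) * match + nmis * mismatch;
          // extend left: best prefix sum, shortest extension on ties
          int acc = 0, best_l = 0, lext = 0;
          for (int t = 1; p - t >= 0 && q - t >= 0; ++t) {
            acc += (genome[p - t] == s[q - t]) ? match : mismatch;
            if (acc > best_l) { best_l = acc; lext = t; }
          }
          // extend right
          acc = 0;
          int best_r = 0, rext = 0;
          for (int t = 0; p + k + t < Lg && q + k + t < Lr; ++t) {
            acc += (genome[p + k + t] == s[q + k + t]) ? match : mismatch;
            if (acc > best_r) { best_r = acc; rext = t + 1; }
          }
          const int score = seed_score + best_l + best_r;
          const int start = p - lext;
          const int end = p + k + rext;
          bool take;
          if (!found) take = true;
          else if (score != b_score) take = score > b_score;
          else if (start != b_start) take = start < b_start;
          else if (strand != b_strand) take = (strand == '+');
          else take = end < b_end;
          if (take) {
            found = true;
            b_score = score; b_start = start; b_end = end;
            b_strand = strand;
          }
        }
      }
    }
    if (found && b_score >= min_score) {
      out_score[i] = b_score; out_start[i] = b_start; out_end[i] = b_end;
      out_strand[i] = (b_strand == '+') ? "+" : "-";
    }
  }
  return DataFrame::create(_["score"] = out_score, _["start"] = out_start,
                           _["end"] = out_end, _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}
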