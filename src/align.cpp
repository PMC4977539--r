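#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; anything but A/C/G/T (upper case) is invalid and
// produces no seed.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  case 'N': return 'N';
  default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[s.size() - 1 - j] = comp_base(s[j]);
    out[i] = r;
  }
  return out;
}

// Exact-match seed index: every k-mer of the forward genome (k <= 31,
// 2-bit packed) mapped to its 0-based start positions in ascending order.
struct SeedIndex {
  std::string genome;
  int k;
  std::unordered_map<uint64_t, std::vector<int> > map;
};

static void fill_index(SeedIndex &idx) {
  const std::string &g = idx.genome;
  const int k = idx.k;
  const int L = (int)g.size();
  if (L < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0; // length of current run of valid bases ending here
  for (int i = 0; i < L; ++i) {
    int c = base_code(g[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx.map[key].push_back(i - k + 1);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string genome, int k) {
  if (k < 1 || k > 31) stop("seed_length must be in [1, 31]");
  if ((int)genome.size() < k)
    stop("genome (%d bases) shorter than seed_length (%d)",
         (int)genome.size(), k);
  XPtr<SeedIndex> p(new SeedIndex(), true);
  p->genome = genome;
  p->k = k;
  fill_index(*p);
  return p;
}

// encode a k-mer; returns false if it contains a non-ACGT base
static bool encode_kmer(const char *s, int k, uint64_t &key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_query_index(SEXP ptr, std::string kmer) {
  XPtr<SeedIndex> idx(ptr);
  if ((int)kmer.size() != idx->k)
    stop("query length %d != seed_length %d", (int)kmer.size(), idx->k);
  uint64_t key;
  if (!encode_kmer(kmer.c_str(), idx->k, key)) return IntegerVector(0);
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
    idx->map.find(key);
  if (it == idx->map.end()) return IntegerVector(0);
  return wrap(it->second);
}

// [[Rcpp::export]]
int cpp_index_n_seeds(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  int n = 0;
  for (std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
         idx->map.begin(); it != idx->map.end(); ++it)
    n += (int)it->second.size();
  return n;
}

// [[Rcpp::export]]
int cpp_index_seed_length(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return idx->k;
}

// [[Rcpp::export]]
std::string cpp_index_genome(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return idx->genome;
}

struct Hit {
  int score, start, end;
  char strand;
  bool found;
  Hit() : score(0), start(0), end(0), strand('+'), found(false) {}
};

// Ungapped extension of the seed genome[p, p+k) ~ seq[q, q+k):
// best-scoring local segment CONTAINING the full seed.  Left/right
// extension lengths are the smallest achieving the running maximum, so
// the reported interval is deterministic.  seed_score is the score of
// the seed window itself (k*match for an exact seed).
static void extend_seed(const std::string &g, const char *s, int slen,
                        int p, int q, int k, int seed_score,
                        int match, int mismatch,
                        int &score, int &start, int &end) {
  int best_l = 0, run = 0, lext = 0;
  for (int i = 1; p - i >= 0 && q - i >= 0; ++i) {
    run += (g[p - i] == s[q - i]) ? match : mismatch;
    if (run > best_l) { best_l = run; lext = i; }
  }
  int best_r = 0, ext = 0;
  run = 0;
  for (int i = 0; p + k + i < (int)g.size() && q + k + i < slen; ++i) {
    run += (g[p + k + i] == s[q + k + i]) ? match : mismatch;
    if (run > best_r) { best_r = run; ext = i + 1; }
  }
  score = seed_score + best_l + best_r;
  start = p - lext;
  end = p + k + ext;
}

// strict improvement comparator shared by the seeded aligner (here) and
// the exhaustive oracle: score desc, then genome start asc, then '+'
// strand, then shortest interval -- total on the reported fields, so the
// result is independent of seed enumeration order.
static inline bool better(int score, int start, int end, char strand,
                          const Hit &h) {
  if (!h.found) return true;
  if (score != h.score) return score > h.score;
  if (start != h.start) return start < h.start;
  if (strand != h.strand) return strand == '+';
  return end < h.end;
}

// probe one seed key against the index and fold hits into `best`
static void probe_key(const SeedIndex &idx, uint64_t key, const char *s,
                      int slen, int q, int seed_score, int match,
                      int mismatch, char strand, Hit &best) {
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
    idx.map.find(key);
  if (it == idx.map.end()) return;
  const std::vector<int> &pos = it->second;
  for (size_t j = 0; j < pos.size(); ++j) {
    int score, start, end;
    extend_seed(idx.genome, s, slen, pos[j], q, idx.k, seed_score,
                match, mismatch, score, start, end);
    if (better(score, start, end, strand, best)) {
      best.score = score; best.start = start; best.end = end;
      best.strand = strand; best.found = true;
    }
  }
}

static void align_one(const std::string &read, const SeedIndex &idx,
                      int seed_mismatches, int match, int mismatch,
                      bool both_strands, Hit &best) {
  const int k = idx.k;
  const int L = (int)read.size();
  best = Hit();
  if (L < k) return;
  std::string rc_str(L, 'N');
  for (int j = 0; j < L; ++j) rc_str[L - 1 - j] = comp_base(read[j]);
  const int n_strands = both_strands ? 2 : 1;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int si = 0; si < n_strands; ++si) {
    const char strand = (si == 0) ? '+' : '-';
    const char *s = (si == 0) ? read.c_str() : rc_str.c_str();
    uint64_t key = 0;
    int valid = 0;
    for (int qe = 0; qe < L; ++qe) {
      int c = base_code(s[qe]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      const int q = qe - k + 1;
      probe_key(idx, key, s, L, q, k * match, match, mismatch, strand, best);
      if (seed_mismatches >= 1) {
        // all single-base variants of the seed
        for (int t = 0; t < k; ++t) {
          const int shift = 2 * (k - 1 - t);
          const uint64_t cur = (key >> shift) & 3ULL;
          for (uint64_t b = 0; b < 4; ++b) {
            if (b == cur) continue;
            const uint64_t vkey =
              (key & ~(3ULL << shift)) | (b << shift);
            probe_key(idx, vkey, s, L, q, (k - 1) * match + mismatch,
                      match, mismatch, strand, best);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads, SEXP ptr,
                          int seed_mismatches, int match, int mismatch,
                          int min_score, bool both_strands) {
  XPtr<SeedIndex> idx(ptr);
  int n = reads.size();
  IntegerVector score(n, NA_INTEGER), start(n, NA_INTEGER),
    end(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  Hit h;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    align_one(r, *idx, seed_mismatches, match, mismatch, both_strands, h);
    if (h.found && h.score >= min_score) {
      score[i] = h.score; start[i] = h.start; end[i] = h.end;
      strand[i] = (h.strand == '+') ? "+" : "-";
    }
  }
  return DataFrame::create(_["score"] = score, _["start"] = start,
                           _["end"] = end, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
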