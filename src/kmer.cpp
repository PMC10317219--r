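#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer machinery shared by the locus index and the classifier.
// k is limited to 31 so a k-mer fits in two bits per base of a uint64.

typedef std::unordered_map<uint64_t, uint16_t> LocusMap;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// Enumerate canonical k-mers of s (windows containing non-ACGT are skipped).
template <typename F>
static void for_each_canonical(const char *s, int n, int k, F f) {
  if (n < k) return;
  uint64_t mask = ((uint64_t)1 << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  int shift = 2 * (k - 1);
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector seqs, IntegerVector locus, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  LocusMap *m = new LocusMap();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP sx = STRING_ELT(seqs, i);
    if (sx == NA_STRING) continue;
    uint16_t bit = (uint16_t)(1u << (locus[i] - 1));
    for_each_canonical(CHAR(sx), (int)LENGTH(sx), k,
                       [&](uint64_t c) { (*m)[c] |= bit; });
  }
  XPtr<LocusMap> p(m, true);
  return p;
}

// external pointers deserialize to NULL; callers rebuild when this is false
// [[Rcpp::export]]
bool xptr_valid_cpp(SEXP p) { return R_ExternalPtrAddr(p) != NULL; }

// [[Rcpp::export]]
double kmer_index_size_cpp(SEXP ptr) {
  XPtr<LocusMap> p(ptr);
  return (double)p->size();
}

// Count matching canonical k-mers per locus over both mates; return the
// winning locus (1-based) when its count reaches min_hits, 0 otherwise.
// Ties between loci are conservative: 0.
// [[Rcpp::export]]
IntegerVector kmer_classify_cpp(SEXP ptr, CharacterVector r1, CharacterVector r2,
                                int k, int n_loci, int min_hits) {
  XPtr<LocusMap> p(ptr);
  LocusMap &m = *p;
  R_xlen_t n = r1.size();
  IntegerVector out(n);
  std::vector<int> counts((size_t)n_loci);
  bool paired = r2.size() == n;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int mate = 0; mate < (paired ? 2 : 1); ++mate) {
      SEXP sx = mate == 0 ? STRING_ELT(r1, i) : STRING_ELT(r2, i);
      if (sx == NA_STRING) continue;
      for_each_canonical(CHAR(sx), (int)LENGTH(sx), k, [&](uint64_t c) {
        LocusMap::iterator it = m.find(c);
        if (it == m.end()) return;
        uint16_t bits = it->second;
        for (int l = 0; l < n_loci; ++l)
          if (bits & (1u << l)) counts[(size_t)l]++;
      });
    }
    int best = 0, besti = 0;
    bool tie = false;
    for (int l = 0; l < n_loci; ++l) {
      if (counts[(size_t)l] > best) { best = counts[(size_t)l]; besti = l + 1; tie = false; }
      else if (counts[(size_t)l] == best && best > 0) tie = true;
    }
    out[i] = (best >= min_hits && !tie) ? besti : 0;
  }
  return out;
}

// Number of distinct canonical k-mers in one sequence (exposed for tests
// against direct enumeration).
// [[Rcpp::export]]
double count_canonical_kmers_cpp(std::string seq, int k) {
  std::unordered_map<uint64_t, uint16_t> seen;
  for_each_canonical(seq.c_str(), (int)seq.size(), k,
                     [&](uint64_t c) { seen[c] = 1; });
  return (double)seen.size();
}
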