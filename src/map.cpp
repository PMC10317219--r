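#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend ungapped read mapper used for OTU depth/coverage and
// organelle read recruitment.  A read maps where an exact k_seed match
// anchors an ungapped extension with identity >= min_identity over the
// read/reference overlap.  Each read is assigned to at most one reference:
// best identity, then longer overlap, then lower reference index (callers
// pass references sorted by identifier).

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static std::string rc_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: r[i] = 'N'; break;
    }
  }
  return r;
}

struct SeedHit { int ref; int pos; };

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector refs, CharacterVector reads, int k_seed,
                   double min_identity, int min_overlap) {
  if (k_seed < 4 || k_seed > 31) stop("k_seed must be between 4 and 31");
  int nref = (int)refs.size();
  uint64_t mask = ((uint64_t)1 << (2 * k_seed)) - 1;
  std::vector<std::string> rseq(nref);
  std::unordered_map<uint64_t, std::vector<SeedHit> > seeds;
  for (int r = 0; r < nref; ++r) {
    rseq[(size_t)r] = as<std::string>(refs[r]);
    const std::string &s = rseq[(size_t)r];
    uint64_t fwd = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[(size_t)i]);
      if (b < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++run >= k_seed) {
        SeedHit h;
        h.ref = r;
        h.pos = i - k_seed + 1;
        seeds[fwd].push_back(h);
      }
    }
  }

  R_xlen_t n = reads.size();
  IntegerVector ref_idx(n), start(n), end(n), mism(n);
  IntegerVector strand(n);
  std::vector<std::vector<int> > pile((size_t)nref);
  for (int r = 0; r < nref; ++r)
    pile[(size_t)r].assign(rseq[(size_t)r].size(), 0);

  std::unordered_set<uint64_t> tried;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) { ref_idx[i] = 0; continue; }
    std::string fw = CHAR(sx);
    std::string rv = rc_str(fw);
    int rl = (int)fw.size();
    double best_id = -1;
    int best_span = -1, best_ref = -1, best_rs = 0, best_re = 0, best_mm = 0;
    int best_strand = 0;
    tried.clear();
    for (int o = 0; o < 2; ++o) {
      const std::string &rd = o == 0 ? fw : rv;
      uint64_t fwd = 0;
      int run = 0;
      for (int p = 0; p < rl; ++p) {
        int b = base2bit(rd[(size_t)p]);
        if (b < 0) { run = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        if (++run < k_seed) continue;
        std::unordered_map<uint64_t, std::vector<SeedHit> >::iterator it =
            seeds.find(fwd);
        if (it == seeds.end()) continue;
        int rpos = p - k_seed + 1;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int ref = it->second[h].ref;
          int diag = it->second[h].pos - rpos;
          uint64_t key = ((uint64_t)o << 62) | ((uint64_t)ref << 33) |
                         (uint64_t)(uint32_t)(diag + (1 << 30));
          if (!tried.insert(key).second) continue;
          const std::string &rs_ = rseq[(size_t)ref];
          int reflen = (int)rs_.size();
          int a = std::max(0, diag);
          int e = std::min(reflen, diag + rl);
          int span = e - a;
          if (span < min_overlap) continue;
          int mm = 0;
          for (int q = a; q < e; ++q)
            if (rs_[(size_t)q] != rd[(size_t)(q - diag)]) ++mm;
          double ident = 1.0 - (double)mm / (double)span;
          if (ident < min_identity) continue;
          bool better = false;
          if (ident > best_id) better = true;
          else if (ident == best_id && span > best_span) better = true;
          else if (ident == best_id && span == best_span && ref < best_ref)
            better = true;
          if (better) {
            best_id = ident;
            best_span = span;
            best_ref = ref;
            best_rs = a;
            best_re = e;
            best_mm = mm;
            best_strand = o == 0 ? 1 : -1;
          }
        }
      }
    }
    if (best_ref >= 0) {
      ref_idx[i] = best_ref + 1;
      start[i] = best_rs;
      end[i] = best_re;
      mism[i] = best_mm;
      strand[i] = best_strand;
      std::vector<int> &pl = pile[(size_t)best_ref];
      for (int q = best_rs; q < best_re; ++q) pl[(size_t)q]++;
    } else {
      ref_idx[i] = 0;
    }
  }

  List pileups(nref);
  for (int r = 0; r < nref; ++r)
    pileups[r] = IntegerVector(pile[(size_t)r].begin(), pile[(size_t)r].end());
  return List::create(_["ref"] = ref_idx, _["strand"] = strand,
                      _["start"] = start, _["end"] = end,
                      _["mismatches"] = mism, _["pileups"] = pileups);
}
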