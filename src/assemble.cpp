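#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimal de Bruijn assembler over canonical k-mers.  Nodes are canonical
// k-mers with count >= min_count; unitigs are maximal non-branching paths.
// Graph cleaning removes short dead-end tips and low-coverage bubble arms,
// then the surviving k-mer set is re-threaded so cleaned paths merge.

typedef std::unordered_map<uint64_t, uint32_t> KmerCount;

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

static inline uint64_t canon(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return x < r ? x : r;
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char *b = "ACGT";
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = b[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static std::string rc_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    }
  }
  return r;
}

// oriented successors / predecessors
static int out_nbrs(const KmerCount &cnt, uint64_t v, int k, uint64_t mask,
                    uint64_t out[4]) {
  int n = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    uint64_t w = ((v << 2) | b) & mask;
    if (cnt.count(canon(w, k))) out[n++] = w;
  }
  return n;
}

static int in_nbrs(const KmerCount &cnt, uint64_t v, int k, uint64_t out[4]) {
  int n = 0;
  int shift = 2 * (k - 1);
  for (uint64_t b = 0; b < 4; ++b) {
    uint64_t w = (v >> 2) | (b << shift);
    if (cnt.count(canon(w, k))) out[n++] = w;
  }
  return n;
}

struct Unitig {
  std::vector<uint64_t> oriented;  // oriented k-mer walk
  std::vector<uint64_t> canonical; // canonical form of each step
  double cov;
  int left_deg, right_deg;
  uint64_t left_nbr, right_nbr;    // canonical unique neighbour (deg == 1)
};

static void build_unitigs(const KmerCount &cnt, int k, uint64_t mask,
                          std::vector<Unitig> &out) {
  out.clear();
  std::vector<uint64_t> keys;
  keys.reserve(cnt.size());
  for (KmerCount::const_iterator it = cnt.begin(); it != cnt.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  std::unordered_set<uint64_t> visited;
  uint64_t nb[4];
  for (size_t ki = 0; ki < keys.size(); ++ki) {
    uint64_t c = keys[ki];
    if (visited.count(c)) continue;
    // forward extension from c's forward orientation
    std::vector<uint64_t> path;
    std::unordered_set<uint64_t> in_path;
    path.push_back(c);
    in_path.insert(c);
    while (true) {
      uint64_t u = path.back();
      if (out_nbrs(cnt, u, k, mask, nb) != 1) break;
      uint64_t w = nb[0];
      if (in_nbrs(cnt, w, k, nb) != 1) break;
      uint64_t cw = canon(w, k);
      if (visited.count(cw) || in_path.count(cw)) break;
      path.push_back(w);
      in_path.insert(cw);
    }
    // backward extension: extend forward from revcomp of the first node
    std::vector<uint64_t> back;
    {
      uint64_t v0 = rc_kmer(path.front(), k);
      uint64_t cur = v0;
      while (true) {
        if (out_nbrs(cnt, cur, k, mask, nb) != 1) break;
        uint64_t w = nb[0];
        if (in_nbrs(cnt, w, k, nb) != 1) break;
        uint64_t cw = canon(w, k);
        if (visited.count(cw) || in_path.count(cw)) break;
        back.push_back(w);
        in_path.insert(cw);
        cur = w;
      }
    }
    Unitig u;
    for (size_t i = back.size(); i > 0; --i)
      u.oriented.push_back(rc_kmer(back[i - 1], k));
    for (size_t i = 0; i < path.size(); ++i) u.oriented.push_back(path[i]);
    double tot = 0;
    for (size_t i = 0; i < u.oriented.size(); ++i) {
      uint64_t cc = canon(u.oriented[i], k);
      u.canonical.push_back(cc);
      visited.insert(cc);
      tot += cnt.at(cc);
    }
    u.cov = tot / (double)u.oriented.size();
    int nl = in_nbrs(cnt, u.oriented.front(), k, nb);
    u.left_deg = nl;
    u.left_nbr = nl == 1 ? canon(nb[0], k) : 0;
    int nr = out_nbrs(cnt, u.oriented.back(), k, mask, nb);
    u.right_deg = nr;
    u.right_nbr = nr == 1 ? canon(nb[0], k) : 0;
    out.push_back(u);
  }
}

// [[Rcpp::export]]
List assemble_bin_cpp(CharacterVector reads, int k, int min_count,
                      double bubble_frac, int tip_len, int min_len,
                      int clean_rounds, double rel_frac) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  if (k % 2 == 0) stop("k must be odd");
  uint64_t mask = ((uint64_t)1 << (2 * k)) - 1;
  KmerCount cnt;
  int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    const char *s = CHAR(sx);
    int n = (int)LENGTH(sx);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int j = 0; j < n; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) cnt[fwd < rev ? fwd : rev]++;
    }
  }
  for (KmerCount::iterator it = cnt.begin(); it != cnt.end();) {
    if ((int)it->second < min_count) it = cnt.erase(it);
    else ++it;
  }

  // per-component relative coverage threshold: within each connected
  // component of the graph, k-mers far below the component's median count
  // are sequencing-error paths (duplicated errors scale with depth, real
  // low-abundance sources keep uniformly moderate counts)
  if (rel_frac > 0 && !cnt.empty()) {
    std::vector<uint64_t> keys;
    keys.reserve(cnt.size());
    for (KmerCount::const_iterator it = cnt.begin(); it != cnt.end(); ++it)
      keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());
    std::unordered_map<uint64_t, int> comp;
    comp.reserve(keys.size());
    int ncomp = 0;
    uint64_t nb[4];
    std::vector<uint64_t> stack;
    for (size_t i = 0; i < keys.size(); ++i) {
      if (comp.count(keys[i])) continue;
      int id = ncomp++;
      stack.push_back(keys[i]);
      comp[keys[i]] = id;
      while (!stack.empty()) {
        uint64_t v = stack.back();
        stack.pop_back();
        for (int side = 0; side < 2; ++side) {
          uint64_t o = side == 0 ? v : rc_kmer(v, k);
          int n1 = out_nbrs(cnt, o, k, mask, nb);
          for (int j = 0; j < n1; ++j) {
            uint64_t c2 = canon(nb[j], k);
            if (!comp.count(c2)) { comp[c2] = id; stack.push_back(c2); }
          }
        }
      }
    }
    std::vector<std::vector<uint32_t> > counts_by((size_t)ncomp);
    for (size_t i = 0; i < keys.size(); ++i)
      counts_by[(size_t)comp[keys[i]]].push_back(cnt[keys[i]]);
    // coverage-weighted median: the count level below which half of the
    // component's coverage mass lies.  A plain median fails at high depth,
    // where duplicated-error k-mers outnumber genuine ones.
    std::vector<double> cutoff((size_t)ncomp, 0);
    for (int c = 0; c < ncomp; ++c) {
      std::vector<uint32_t> &v = counts_by[(size_t)c];
      std::sort(v.begin(), v.end());
      double tot = 0;
      for (size_t j = 0; j < v.size(); ++j) tot += v[j];
      double acc = 0;
      uint32_t wmed = v.back();
      for (size_t j = 0; j < v.size(); ++j) {
        acc += v[j];
        if (acc >= tot / 2) { wmed = v[j]; break; }
      }
      cutoff[(size_t)c] = rel_frac * (double)wmed;
    }
    for (size_t i = 0; i < keys.size(); ++i)
      if ((double)cnt[keys[i]] < cutoff[(size_t)comp[keys[i]]])
        cnt.erase(keys[i]);
  }

  // local relative-abundance cleanup: a k-mer far below its strongest
  // graph neighbour is a sequencing-error branch at high depth; genuine
  // low-abundance components keep uniformly low counts and survive
  if (rel_frac > 0) {
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<uint64_t> weak;
      uint64_t nb[4];
      for (KmerCount::const_iterator it = cnt.begin(); it != cnt.end();
           ++it) {
        uint64_t v = it->first;  // canonical orientation
        uint32_t best = 0;
        int n1 = out_nbrs(cnt, v, k, mask, nb);
        for (int j = 0; j < n1; ++j)
          best = std::max(best, cnt.at(canon(nb[j], k)));
        int n2 = in_nbrs(cnt, v, k, nb);
        for (int j = 0; j < n2; ++j)
          best = std::max(best, cnt.at(canon(nb[j], k)));
        if ((double)it->second < rel_frac * (double)best)
          weak.push_back(v);
      }
      if (weak.empty()) break;
      for (size_t j = 0; j < weak.size(); ++j) cnt.erase(weak[j]);
    }
  }

  std::vector<Unitig> unis;
  for (int round = 0; round < clean_rounds; ++round) {
    build_unitigs(cnt, k, mask, unis);
    std::vector<char> drop(unis.size(), 0);
    // tips: one dead end, short
    for (size_t i = 0; i < unis.size(); ++i) {
      const Unitig &u = unis[i];
      bool left_dead = u.left_deg == 0, right_dead = u.right_deg == 0;
      int len = (int)u.oriented.size() + k - 1;
      if ((left_dead != right_dead) && len < tip_len) drop[i] = 1;
    }
    // bubbles: unitigs sharing both unique junction neighbours
    std::map<std::pair<uint64_t, uint64_t>, std::vector<size_t> > groups;
    for (size_t i = 0; i < unis.size(); ++i) {
      const Unitig &u = unis[i];
      if (drop[i] || u.left_deg != 1 || u.right_deg != 1) continue;
      std::pair<uint64_t, uint64_t> key(std::min(u.left_nbr, u.right_nbr),
                                        std::max(u.left_nbr, u.right_nbr));
      groups[key].push_back(i);
    }
    for (std::map<std::pair<uint64_t, uint64_t>,
                  std::vector<size_t> >::iterator g = groups.begin();
         g != groups.end(); ++g) {
      if (g->second.size() < 2) continue;
      double maxcov = 0;
      for (size_t j = 0; j < g->second.size(); ++j)
        maxcov = std::max(maxcov, unis[g->second[j]].cov);
      for (size_t j = 0; j < g->second.size(); ++j) {
        size_t i = g->second[j];
        if (unis[i].cov < bubble_frac * maxcov) drop[i] = 1;
      }
    }
    bool any = false;
    for (size_t i = 0; i < unis.size(); ++i) {
      if (!drop[i]) continue;
      any = true;
      for (size_t j = 0; j < unis[i].canonical.size(); ++j)
        cnt.erase(unis[i].canonical[j]);
    }
    if (!any) break;
  }
  build_unitigs(cnt, k, mask, unis);

  std::vector<std::pair<std::string, double> > res;
  for (size_t i = 0; i < unis.size(); ++i) {
    const Unitig &u = unis[i];
    int len = (int)u.oriented.size() + k - 1;
    if (len < min_len) continue;
    std::string s = decode_kmer(u.oriented.front(), k);
    for (size_t j = 1; j < u.oriented.size(); ++j)
      s.push_back("ACGT"[u.oriented[j] & 3ULL]);
    std::string r = rc_str(s);
    res.push_back(std::make_pair(r < s ? r : s, u.cov));
  }
  std::sort(res.begin(), res.end());
  CharacterVector seqs((R_xlen_t)res.size());
  NumericVector covs((R_xlen_t)res.size());
  for (size_t i = 0; i < res.size(); ++i) {
    seqs[(R_xlen_t)i] = res[i].first;
    covs[(R_xlen_t)i] = res[i].second;
  }
  return List::create(_["seq"] = seqs, _["coverage"] = covs);
}
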