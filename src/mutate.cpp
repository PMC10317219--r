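#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Substitution-only sequencing error model.  The per-base substitution
// probability ramps linearly along the read so that the 3' end has twice
// the rate of the 5' end while the mean over the read equals `rate`:
//   p(i) = rate * (2/3) * (1 + i/(L-1)).
// Uses the R RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
CharacterVector mutate_reads_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = { 'A', 'C', 'G', 'T' };
  RNGScope scope;
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sx = STRING_ELT(seqs, i);
    if (sx == NA_STRING) { out[i] = NA_STRING; continue; }
    buf.assign(CHAR(sx), (size_t)LENGTH(sx));
    int L = (int)buf.size();
    double denom = L > 1 ? (double)(L - 1) : 1.0;
    for (int j = 0; j < L; ++j) {
      double p = rate * (2.0 / 3.0) * (1.0 + (double)j / denom);
      if (unif_rand() >= p) continue;
      char c = buf[(size_t)j];
      int cur;
      switch (c) {
      case 'A': cur = 0; break;
      case 'C': cur = 1; break;
      case 'G': cur = 2; break;
      case 'T': cur = 3; break;
      default: continue;
      }
      int off = 1 + (int)(unif_rand() * 3.0);
      if (off > 3) off = 3;
      buf[(size_t)j] = bases[(cur + off) % 4];
    }
    out[i] = buf;
  }
  return out;
}
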