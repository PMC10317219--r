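#include <Rcpp.h>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quality trimming: drop leading bases below leading_q and trailing bases
// below trailing_q, then cut before the first sliding window (length
// `window`) whose mean quality falls below min_mean_q.  Returns 1-based
// [start, end] of the retained region per read; end < start means empty.

// [[Rcpp::export]]
IntegerMatrix quality_trim_cpp(CharacterVector quals, int window,
                               double min_mean_q, int leading_q,
                               int trailing_q, int phred_offset) {
  R_xlen_t n = quals.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sx = STRING_ELT(quals, i);
    if (sx == NA_STRING) { out(i, 0) = 1; out(i, 1) = 0; continue; }
    const char *q = CHAR(sx);
    int len = (int)LENGTH(sx);
    int s = 0, e = len - 1;
    while (s < len && (q[s] - phred_offset) < leading_q) ++s;
    while (e >= s && (q[e] - phred_offset) < trailing_q) --e;
    if (window > 0 && e - s + 1 >= window) {
      double sum = 0;
      for (int j = s; j < s + window; ++j) sum += q[j] - phred_offset;
      int cut = -1;
      for (int w = s; w + window - 1 <= e; ++w) {
        if (w > s) sum += (q[w + window - 1] - phred_offset) -
                          (q[w - 1] - phred_offset);
        if (sum / window < min_mean_q) { cut = w; break; }
      }
      if (cut >= 0) e = cut - 1;
    }
    out(i, 0) = s + 1;
    out(i, 1) = e + 1;
  }
  return out;
}

// Adapter clipping: remove the read suffix from the leftmost position where
// a prefix of the adapter aligns to it with >= min_overlap bases and a
// mismatch rate <= max_mismatch_rate.  Returns the retained length.

// [[Rcpp::export]]
IntegerVector clip_adapter_cpp(CharacterVector seqs, std::string adapter,
                               int min_overlap, double max_mismatch_rate) {
  R_xlen_t n = seqs.size();
  int alen = (int)adapter.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sx = STRING_ELT(seqs, i);
    if (sx == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(sx);
    int len = (int)LENGTH(sx);
    int keep = len;
    for (int p = 0; p <= len - min_overlap; ++p) {
      int ov = std::min(len - p, alen);
      if (ov < min_overlap) break;
      int allowed = (int)std::floor(max_mismatch_rate * ov);
      int mm = 0;
      for (int j = 0; j < ov && mm <= allowed; ++j)
        if (s[p + j] != adapter[(size_t)j]) ++mm;
      if (mm <= allowed) { keep = p; break; }
    }
    out[i] = keep;
  }
  return out;
}
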