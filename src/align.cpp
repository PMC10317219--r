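#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Overlap (end-gap-free) pairwise alignment with affine gaps.  Terminal gaps
// on either sequence are free; the score is maximised over the last row and
// column.  Gap scoring: the first column of a gap costs gap_open, each
// further column gap_ext.  Returns score, base differences (mismatch + gap
// columns inside the aligned overlap) and the aligned span (columns).

// [[Rcpp::export]]
NumericVector overlap_align_cpp(std::string a, std::string b, double match,
                                double mismatch, double gap_open,
                                double gap_ext) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return NumericVector::create(_["score"] = 0, _["base_differences"] = 0,
                                 _["aligned_span"] = 0);
  const double NEG = -1e15;
  size_t W = (size_t)(m + 1);
  std::vector<double> M((size_t)(n + 1) * W, NEG), X = M, Y = M;
  // trace: which state preceded (0=M,1=X,2=Y)
  std::vector<signed char> tM((size_t)(n + 1) * W, 0), tX = tM, tY = tM;
  for (int j = 0; j <= m; ++j) M[(size_t)j] = 0;   // free leading gap in a
  for (int i = 0; i <= n; ++i) M[(size_t)i * W] = 0; // free leading gap in b
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t ij = (size_t)i * W + (size_t)j;
      size_t pd = (size_t)(i - 1) * W + (size_t)(j - 1);
      size_t pu = (size_t)(i - 1) * W + (size_t)j;
      size_t pl = ij - 1;
      double s = (a[(size_t)(i - 1)] == b[(size_t)(j - 1)]) ? match : mismatch;
      double bm = M[pd];
      signed char tb = 0;
      if (X[pd] > bm) { bm = X[pd]; tb = 1; }
      if (Y[pd] > bm) { bm = Y[pd]; tb = 2; }
      M[ij] = bm + s;
      tM[ij] = tb;
      // X: gap in b (consume a[i])
      double xo = M[pu] + gap_open, xe = X[pu] + gap_ext;
      if (xo >= xe) { X[ij] = xo; tX[ij] = 0; } else { X[ij] = xe; tX[ij] = 1; }
      // Y: gap in a (consume b[j])
      double yo = M[pl] + gap_open, ye = Y[pl] + gap_ext;
      if (yo >= ye) { Y[ij] = yo; tY[ij] = 0; } else { Y[ij] = ye; tY[ij] = 2; }
    }
  }
  // best end on last row / last column; prefer state M, then X, then Y
  double best = NEG;
  int bi = n, bj = m, bs = 0;
  for (int j = m; j >= 1; --j) {
    size_t ij = (size_t)n * W + (size_t)j;
    double v[3] = { M[ij], X[ij], Y[ij] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; bi = n; bj = j; bs = s; }
  }
  for (int i = n; i >= 1; --i) {
    size_t ij = (size_t)i * W + (size_t)m;
    double v[3] = { M[ij], X[ij], Y[ij] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; bi = i; bj = m; bs = s; }
  }
  if (best <= NEG / 2) best = 0;
  // traceback
  int i = bi, j = bj, st = bs;
  int mismatches = 0, gapcols = 0, span = 0;
  while (i > 0 && j > 0) {
    size_t ij = (size_t)i * W + (size_t)j;
    if (st == 0) {
      span++;
      if (a[(size_t)(i - 1)] != b[(size_t)(j - 1)]) mismatches++;
      st = tM[ij];
      --i; --j;
    } else if (st == 1) {
      span++; gapcols++;
      st = tX[ij];
      --i;
    } else {
      span++; gapcols++;
      st = tY[ij];
      --j;
    }
  }
  return NumericVector::create(_["score"] = best,
                               _["base_differences"] = mismatches + gapcols,
                               _["aligned_span"] = span);
}
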