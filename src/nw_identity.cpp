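#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment under unit edit costs:
// match 0, mismatch 1, gap 1. Identity is the fraction of alignment
// columns (gap columns included) that are exact matches, taken from a
// deterministic traceback that prefers diagonal > up > left on ties so
// the value is reproducible across platforms and oracles.

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0)
    stop("sequences must be nonempty");
  // DP matrix of edit costs, row-major (la+1) x (lb+1)
  std::vector<int> d((la + 1) * (lb + 1));
  const int w = lb + 1;
  for (int i = 0; i <= la; ++i) d[i * w] = i;
  for (int j = 0; j <= lb; ++j) d[j] = j;
  for (int i = 1; i <= la; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int sub = d[(i - 1) * w + (j - 1)] + (ai == b[j - 1] ? 0 : 1);
      int del = d[(i - 1) * w + j] + 1;
      int ins = d[i * w + (j - 1)] + 1;
      int best = sub < del ? sub : del;
      if (ins < best) best = ins;
      d[i * w + j] = best;
    }
  }
  // traceback: diagonal preferred, then up (gap in b), then left
  int i = la, j = lb;
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      int sub = d[(i - 1) * w + (j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (d[i * w + j] == sub) {
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j; ++cols;
        continue;
      }
    }
    if (i > 0 && d[i * w + j] == d[(i - 1) * w + j] + 1) {
      --i; ++cols;
      continue;
    }
    --j; ++cols;
  }
  return (double)matches / (double)cols;
}
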