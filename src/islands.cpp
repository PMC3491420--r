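#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive CpG-island candidate scan.
//
// For every start position s, find the longest end e (s + min_len <= e <=
// s + max_len) such that the window [s, e) satisfies all three island
// criteria:
//   GC content  (nC + nG) / L        >= min_gc
//   CpG obs/exp (nCpG * L)/(nC * nG) >= min_oe   (undefined, hence failing,
//                                                 when nC or nG is zero)
//   length      L                    >= min_len
// `code` encodes the sequence as A=0, C=1, G=2, T=3, other=4; CpGs are
// counted on the plus strand (C at p, G at p+1). Returns the qualifying
// starts with their longest qualifying ends (0-based half-open); clustering
// into overlap components and picking one maximal interval per component is
// done in R.
// [[Rcpp::export]]
List scan_island_candidates(IntegerVector code, double min_oe, double min_gc,
                            int min_len, int max_len) {
  const int n = code.size();
  std::vector<int> out_start, out_end;
  if (n >= min_len) {
    std::vector<int> pc(n + 1, 0), pg(n + 1, 0), pcg(n + 1, 0);
    for (int i = 0; i < n; i++) {
      pc[i + 1] = pc[i] + (code[i] == 1);
      pg[i + 1] = pg[i] + (code[i] == 2);
      pcg[i + 1] = pcg[i] + (i + 1 < n && code[i] == 1 && code[i + 1] == 2);
    }
    for (int s = 0; s <= n - min_len; s++) {
      const int emax = std::min(n, s + max_len);
      int best = -1;
      for (int e = s + min_len; e <= emax; e++) {
        const int L = e - s;
        const int nC = pc[e] - pc[s];
        const int nG = pg[e] - pg[s];
        if (nC == 0 || nG == 0) continue;
        if ((double)(nC + nG) < min_gc * L) continue;
        // CpGs fully inside the window: C at p in [s, e - 1)
        const int nCG = pcg[e - 1] - pcg[s];
        if ((double)nCG * L < min_oe * (double)nC * (double)nG) continue;
        best = e;
      }
      if (best > 0) {
        out_start.push_back(s);
        out_end.push_back(best);
      }
    }
  }
  return List::create(_["start"] = wrap(out_start), _["end"] = wrap(out_end));
}
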