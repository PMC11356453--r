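#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-layer DP) with a fixed,
// deterministic tie-break during traceback: at equal score a column is
// resolved as match/mismatch first, then gap-in-candidate (candidate row
// shows '-'), then gap-in-reference.
//
// ref, cand: 0-based indices into the rows/columns of `sub`.
// A gap run of length L costs gap_open + L * gap_extend.
//
// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(IntegerVector ref, IntegerVector cand, NumericMatrix sub,
               double gap_open, double gap_extend) {
  const int n = ref.size(), m = cand.size();
  const double NEG = -1e18;
  const double open_col = gap_open + gap_extend; // first column of a gap run

  std::vector<double> H((n + 1) * (m + 1), NEG);
  std::vector<double> GC((n + 1) * (m + 1), NEG); // gap in candidate (consumes ref)
  std::vector<double> GR((n + 1) * (m + 1), NEG); // gap in reference (consumes cand)
  // ptrH: 0 diag, 1 enter GC, 2 enter GR; ptrGC/ptrGR: 0 open (from H), 1 extend
  std::vector<signed char> ptrH((n + 1) * (m + 1), 0);
  std::vector<signed char> ptrGC((n + 1) * (m + 1), 0);
  std::vector<signed char> ptrGR((n + 1) * (m + 1), 0);

  const int W = m + 1;
  H[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    GC[i * W] = -(gap_open + gap_extend * i);
    H[i * W] = GC[i * W];
    ptrH[i * W] = 1;
    ptrGC[i * W] = 1;
  }
  ptrGC[1 * W] = 0;
  for (int j = 1; j <= m; ++j) {
    GR[j] = -(gap_open + gap_extend * j);
    H[j] = GR[j];
    ptrH[j] = 2;
    ptrGR[j] = 1;
  }
  ptrGR[1] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      double op = H[(i - 1) * W + j] - open_col;
      double ex = GC[(i - 1) * W + j] - gap_extend;
      if (ex > op) { GC[c] = ex; ptrGC[c] = 1; } else { GC[c] = op; ptrGC[c] = 0; }

      op = H[i * W + (j - 1)] - open_col;
      ex = GR[i * W + (j - 1)] - gap_extend;
      if (ex > op) { GR[c] = ex; ptrGR[c] = 1; } else { GR[c] = op; ptrGR[c] = 0; }

      const double diag = H[(i - 1) * W + (j - 1)] + sub(ref[i - 1], cand[j - 1]);
      double best = diag;
      signed char p = 0;
      if (GC[c] > best) { best = GC[c]; p = 1; }
      if (GR[c] > best) { best = GR[c]; p = 2; }
      H[c] = best;
      ptrH[c] = p;
    }
  }

  std::string ra, ca;
  ra.reserve(n + m);
  ca.reserve(n + m);
  int i = n, j = m, layer = 0;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (layer == 0) {
      const signed char p = ptrH[c];
      if (p == 0) {
        ra.push_back((char)(ref[i - 1]));
        ca.push_back((char)(cand[j - 1]));
        --i; --j;
      } else {
        layer = p; // enter gap layer without emitting
      }
    } else if (layer == 1) { // gap in candidate: consume ref
      ra.push_back((char)(ref[i - 1]));
      ca.push_back((char)(-1));
      if (ptrGC[c] == 0) layer = 0;
      --i;
    } else { // gap in reference: consume cand
      ra.push_back((char)(-1));
      ca.push_back((char)(cand[j - 1]));
      if (ptrGR[c] == 0) layer = 0;
      --j;
    }
  }

  const int L = ra.size();
  IntegerVector ref_idx(L), cand_idx(L);
  for (int k = 0; k < L; ++k) {
    // reverse order; -1 encodes a gap
    ref_idx[k] = (signed char)ra[L - 1 - k];
    cand_idx[k] = (signed char)ca[L - 1 - k];
  }
  return List::create(_["ref_idx"] = ref_idx, _["cand_idx"] = cand_idx,
                      _["score"] = H[n * W + m]);
}
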