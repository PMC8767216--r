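#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Effective connectivity of a k-input look-up table.
//
// For every LUT entry we need the size of the largest monochromatic
// subcube containing it: a set W of wildcard inputs such that all entries
// agreeing with the entry outside W share its output. The entry then needs
// k - |W| effective inputs ("enputs"); k_e is the mean over the 2^k
// entries. Subcubes are enumerated by dynamic programming: a cube with
// wildcard set W is constant iff its two halves along any w in W are
// constant and agree.
//
// The constancy table is indexed by (mask, base) where mask is the
// wildcard bitmask and base the entry index with masked bits cleared;
// it needs 4^k bytes, so this kernel is restricted to k <= 12 (the R
// wrapper falls back to a schema-based route for larger arities).

static double ke_from_lut(const int* out, int k,
                          std::vector<uint8_t>& mono,
                          std::vector<int>& best) {
  const int S = 1 << k;
  if (k == 0) return 0.0;
  mono.assign((size_t)S * S, 0);
  best.assign(S, 0);

  // mask = 0: single entries are trivially constant
  for (int v = 0; v < S; ++v) mono[v] = 1;

  // bases valid for a mask are the submasks of its complement; enumerate
  // them directly so the fill costs 3^k, not 4^k
  for (int mask = 1; mask < S; ++mask) {
    const int b = mask & (-mask);        // lowest wildcard bit
    const int rest = mask ^ b;
    const int w = __builtin_popcount((unsigned)mask);
    const size_t row = (size_t)mask * S;
    const size_t rrow = (size_t)rest * S;
    const int free_ = (S - 1) & ~mask;
    int v = free_;
    for (;;) {
      const int hi = v | b;
      const bool ok = mono[rrow + v] && mono[rrow + hi] && (out[v] == out[hi]);
      mono[row + v] = ok;
      if (ok) {
        // record the cube on all its members as they are visited later;
        // cheaper: update members now (cubes are sparse for random rules)
        int sub = mask;
        for (;;) {
          const int e = v | sub;
          if (best[e] < w) best[e] = w;
          if (sub == 0) break;
          sub = (sub - 1) & mask;
        }
      }
      if (v == 0) break;
      v = (v - 1) & free_;
    }
  }

  long long acc = 0;
  for (int e = 0; e < S; ++e) acc += k - best[e];
  return (double)acc / (double)S;
}

// [[Rcpp::export(name = ".ke_lut")]]
double ke_lut_cpp(IntegerVector outputs) {
  const int S = outputs.size();
  int k = 0;
  while ((1 << k) < S) ++k;
  if ((1 << k) != S) stop("LUT length must be a power of two");
  if (k > 12) stop("compiled kernel supports k <= 12");
  std::vector<uint8_t> mono;
  std::vector<int> best;
  return ke_from_lut(INTEGER(outputs), k, mono, best);
}

// [[Rcpp::export(name = ".ke_lut_batch")]]
NumericVector ke_lut_batch_cpp(IntegerMatrix outputs) {
  // one rule per row
  const int n = outputs.nrow();
  const int S = outputs.ncol();
  int k = 0;
  while ((1 << k) < S) ++k;
  if ((1 << k) != S) stop("LUT length must be a power of two");
  if (k > 12) stop("compiled kernel supports k <= 12");
  NumericVector res(n);
  std::vector<uint8_t> mono;
  std::vector<int> best;
  std::vector<int> row(S);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < S; ++j) row[j] = outputs(i, j);
    res[i] = ke_from_lut(row.data(), k, mono, best);
  }
  return res;
}
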