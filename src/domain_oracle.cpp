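#include <Rcpp.h>
using namespace Rcpp;

// Brute-force reference for the gap-tolerant domain construction.
// For every binary vector of `len` bins (encoded as the bits of the row
// index), finds the leftmost largest contiguous block of positive bins and
// then the widest interval [a, b] with positive endpoints that contains
// the block and whose internal gaps between consecutive positive bins are
// all < gap_limit.  Deliberately O(P^2 * P) per vector: a different
// algorithm from the production scan, used only for validation.
// [[Rcpp::export]]
IntegerMatrix cpp_domain_oracle_enumerate(int len, int gap_limit) {
  if (len < 1 || len > 25) stop("len must be in 1..25");
  const int n = 1 << len;
  IntegerMatrix out(n, 2);
  std::vector<int> pos;
  pos.reserve(len);
  for (int v = 0; v < n; ++v) {
    pos.clear();
    for (int i = 0; i < len; ++i)
      if (v & (1 << i)) pos.push_back(i);
    if (pos.empty()) {
      out(v, 0) = -1;
      out(v, 1) = -1;
      continue;
    }
    // leftmost largest contiguous block
    int bs = pos[0], be = pos[0], cs = pos[0], ce = pos[0];
    for (size_t k = 1; k < pos.size(); ++k) {
      if (pos[k] == ce + 1) {
        ce = pos[k];
      } else {
        cs = ce = pos[k];
      }
      if (ce - cs > be - bs) { bs = cs; be = ce; }
    }
    // widest valid candidate containing [bs, be]
    int best_a = bs, best_b = be, best_w = be - bs;
    const int P = (int) pos.size();
    for (int i = 0; i < P; ++i) {
      if (pos[i] > bs) break;
      for (int j = P - 1; j >= 0; --j) {
        if (pos[j] < be) break;
        // internal gaps within [pos[i], pos[j]] must all be < gap_limit
        bool ok = true;
        for (int k = i; k < j; ++k) {
          if (pos[k + 1] - pos[k] - 1 >= gap_limit) { ok = false; break; }
        }
        if (ok) {
          int w = pos[j] - pos[i];
          if (w > best_w) { best_w = w; best_a = pos[i]; best_b = pos[j]; }
        }
      }
    }
    out(v, 0) = best_a;
    out(v, 1) = best_b;
  }
  return out;
}
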