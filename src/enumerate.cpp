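// Connected-subset enumeration and cohesion over bitmask subsets.
// Parts are capped at 31 vertices (maxp <= 25 recommended), so a subset is
// one int. The enumeration is the standard duplicate-free anchored scheme:
// subsets containing anchor v but no earlier vertex are grown by extending
// only with never-seen neighbours.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

void extend_subsets(int sub, int ext, int seen, int sz,
                    int min_size, int max_size,
                    const std::vector<int>& nbr, std::vector<int>& out) {
  if (sz >= min_size) out.push_back(sub);
  if (sz == max_size) return;
  while (ext) {
    int u_bit = ext & -ext;
    ext ^= u_bit;
    int u = __builtin_ctz(u_bit);
    int excl = nbr[u] & ~seen;
    extend_subsets(sub | u_bit, ext | excl, seen | excl | u_bit, sz + 1,
                   min_size, max_size, nbr, out);
  }
}

} // namespace

// [[Rcpp::export]]
IntegerVector enum_connected_masks_cpp(int n, IntegerVector ia,
                                       IntegerVector ib,
                                       int min_size, int max_size) {
  if (n > 31) stop("enumeration supports at most 31 vertices per part");
  std::vector<int> nbr(n, 0);
  for (int e = 0; e < ia.size(); ++e) {
    nbr[ia[e] - 1] |= 1 << (ib[e] - 1);
    nbr[ib[e] - 1] |= 1 << (ia[e] - 1);
  }
  std::vector<int> out;
  for (int v = 0; v < n; ++v) {
    int v_bit = 1 << v;
    int forbidden = v_bit - 1;
    int seen0 = nbr[v] | v_bit | forbidden;
    int ext0 = nbr[v] & ~(forbidden | v_bit);
    extend_subsets(v_bit, ext0, seen0, 1, min_size, max_size, nbr, out);
  }
  return wrap(out);
}

// Cohesion of each mask subset: mean over members of
// (within-set strength) * (within-set degree + 1) / |S|.
// [[Rcpp::export]]
NumericVector cohesion_masks_cpp(int n, IntegerVector ia, IntegerVector ib,
                                 NumericVector w, IntegerVector masks) {
  int m = ia.size();
  std::vector<int> ea(m), eb(m), ebit(m);
  for (int e = 0; e < m; ++e) {
    ea[e] = ia[e] - 1;
    eb[e] = ib[e] - 1;
    ebit[e] = (1 << ea[e]) | (1 << eb[e]);
  }
  NumericVector out(masks.size());
  std::vector<double> sm(n);
  std::vector<int> cnt(n);
  for (int s = 0; s < masks.size(); ++s) {
    int mask = masks[s];
    int k = __builtin_popcount(mask);
    std::fill(sm.begin(), sm.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int e = 0; e < m; ++e) {
      if ((mask & ebit[e]) == ebit[e]) {
        sm[ea[e]] += w[e]; sm[eb[e]] += w[e];
        cnt[ea[e]] += 1;  cnt[eb[e]] += 1;
      }
    }
    double acc = 0.0;
    int rest = mask;
    while (rest) {
      int bit = rest & -rest;
      rest ^= bit;
      int v = __builtin_ctz(bit);
      acc += sm[v] * (cnt[v] + 1);
    }
    out[s] = acc / (double(k) * double(k));
  }
  return out;
}
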