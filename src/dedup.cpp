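// Chainwise deduplication: scanning candidates in (cohesion desc, canonical
// key asc) order, a candidate dies when its neighbourhood affinity
// |a & b|^2 / (|a| * |b|) reaches the threshold against ANY earlier
// candidate, kept or deleted. Early exit on the first hit keeps the
// quadratic scan cheap in practice.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Candidates as 31-bit masks over one part's vertices.
// [[Rcpp::export]]
LogicalVector dedup_masks_cpp(IntegerVector masks, double threshold) {
  int n = masks.size();
  LogicalVector keep(n);
  std::vector<int> sz(n);
  for (int i = 0; i < n; ++i) sz[i] = __builtin_popcount(masks[i]);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    double lim = threshold * sz[i];
    for (int j = 0; j < i; ++j) {
      double inter = __builtin_popcount(masks[i] & masks[j]);
      if (inter * inter >= lim * sz[j]) { ok = false; break; }
    }
    keep[i] = ok;
  }
  return keep;
}

// Candidates as sorted integer-coded member vectors (arbitrary universe).
// [[Rcpp::export]]
LogicalVector dedup_sets_cpp(List members, double threshold) {
  int n = members.size();
  std::vector<std::vector<int>> sets(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = members[i];
    sets[i] = std::vector<int>(v.begin(), v.end());
  }
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    double lim = threshold * sets[i].size();
    for (int j = 0; j < i; ++j) {
      // sorted-merge intersection count
      size_t a = 0, b = 0; int inter = 0;
      while (a < sets[i].size() && b < sets[j].size()) {
        if (sets[i][a] < sets[j][b]) ++a;
        else if (sets[i][a] > sets[j][b]) ++b;
        else { ++inter; ++a; ++b; }
      }
      if (double(inter) * inter >= lim * sets[j].size()) { ok = false; break; }
    }
    keep[i] = ok;
  }
  return keep;
}
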