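#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over 1..n
struct Fenwick {
  std::vector<int> t;
  int n;
  Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i) { for (; i <= n; i += i & (-i)) t[i]++; }
  int query(int i) const { int s = 0; for (; i > 0; i -= i & (-i)) s += t[i]; return s; }
};

// For each i, count #{k : p1[k] <= p1[i] && p2[k] <= p2[i]} with inclusive
// ties on both coordinates. O(N log N): sweep in groups of equal p1, insert
// the whole group into a Fenwick tree over p2 ranks before querying members.
// [[Rcpp::export]]
IntegerVector count_joint_le(NumericVector p1, NumericVector p2) {
  int n = p1.size();
  if (p2.size() != n) stop("p1 and p2 must have equal length");
  // dense ranks of p2 (ties share a rank)
  std::vector<int> ord2(n);
  for (int i = 0; i < n; ++i) ord2[i] = i;
  std::sort(ord2.begin(), ord2.end(),
            [&](int a, int b) { return p2[a] < p2[b]; });
  std::vector<int> rank2(n);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && p2[ord2[i]] != p2[ord2[i - 1]]) r = i;
    rank2[ord2[i]] = r + 1;  // 1-based, max rank for ties handled by <= query
  }
  // ties get the same dense rank; querying prefix <= rank includes all ties
  std::vector<int> ord1(n);
  for (int i = 0; i < n; ++i) ord1[i] = i;
  std::sort(ord1.begin(), ord1.end(),
            [&](int a, int b) { return p1[a] < p1[b]; });
  Fenwick fw(n);
  IntegerVector out(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && p1[ord1[j]] == p1[ord1[i]]) ++j;
    for (int k = i; k < j; ++k) fw.add(rank2[ord1[k]]);
    for (int k = i; k < j; ++k) out[ord1[k]] = fw.query(rank2[ord1[k]]);
    i = j;
  }
  return out;
}
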