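#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// Exact k nearest neighbours by brute force, Euclidean metric.
// Ties in distance are broken by the lower event index (pairs sort by
// distance first, then index). Self is excluded. Returns 1-based indices,
// one row per event, ordered nearest first.
// [[Rcpp::export(name = ".brute_knn")]]
IntegerMatrix brute_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of events");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      cand[j] = std::make_pair(s, j);
    }
    cand[i].first = R_PosInf;  // never one's own neighbour
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// Jaccard re-weighting of a kNN graph. The edge set is the symmetrised
// union of directed kNN links; the weight of edge (a, b) is
// |N(a) & N(b)| / |N(a) | N(b)| over the two k-neighbour sets (self
// excluded, the other endpoint may be a member). Zero-weight edges are
// dropped. Each undirected pair is emitted exactly once: while scanning
// node x, the pair (x, y) with y > x is emitted directly, and the pair
// (y, x) with y < x only when x is not in N(y) (otherwise y's own scan
// already produced it). Returns 1-based endpoint vectors plus weights.
// [[Rcpp::export(name = ".knn_jaccard_edges")]]
List knn_jaccard_edges(IntegerMatrix idx) {
  const int n = idx.nrow(), k = idx.ncol();
  std::vector<int> nbr(static_cast<size_t>(n) * k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      const int v = idx(i, j) - 1;
      if (v == i) stop("self-neighbour in kNN index");
      nbr[static_cast<size_t>(i) * k + j] = v;
    }
    std::sort(nbr.begin() + static_cast<size_t>(i) * k,
              nbr.begin() + static_cast<size_t>(i) * k + k);
  }
  std::vector<int> from, to;
  std::vector<double> weight;
  from.reserve(static_cast<size_t>(n) * k);
  to.reserve(static_cast<size_t>(n) * k);
  weight.reserve(static_cast<size_t>(n) * k);
  for (int i = 0; i < n; ++i) {
    const int* Ai = &nbr[static_cast<size_t>(i) * k];
    for (int j = 0; j < k; ++j) {
      const int b = Ai[j];
      if (b < i) {
        // emitted during b's scan iff i is a neighbour of b
        const int* Bb = &nbr[static_cast<size_t>(b) * k];
        if (std::binary_search(Bb, Bb + k, i)) continue;
      }
      const int lo = std::min(i, b), hi = std::max(i, b);
      const int* A = &nbr[static_cast<size_t>(lo) * k];
      const int* B = &nbr[static_cast<size_t>(hi) * k];
      int ia = 0, ib = 0, inter = 0;
      while (ia < k && ib < k) {
        if (A[ia] < B[ib]) ++ia;
        else if (A[ia] > B[ib]) ++ib;
        else { ++inter; ++ia; ++ib; }
      }
      if (inter == 0) continue;  // disjoint neighbourhoods: edge dropped
      from.push_back(lo + 1);
      to.push_back(hi + 1);
      weight.push_back(static_cast<double>(inter) / (2.0 * k - inter));
    }
  }
  return List::create(_["from"] = from, _["to"] = to, _["weight"] = weight);
}
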