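#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Louvain community detection: greedy modularity optimisation with local
// moving in a FIXED node order (ascending index) and lowest-community-id
// tie-breaking, followed by graph aggregation, repeated until no further
// merge. Fully deterministic. Edges are undirected, 1-based, weighted;
// multi-edges are summed.
// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(int n, IntegerVector from, IntegerVector to,
                          NumericVector weight) {
  if (n <= 0) stop("empty graph");
  const double eps = 1e-12;

  std::vector<int> orig2cur(n);
  for (int i = 0; i < n; ++i) orig2cur[i] = i;

  std::vector<int> efrom(from.size()), eto(to.size());
  std::vector<double> ew(weight.size());
  for (R_xlen_t e = 0; e < from.size(); ++e) {
    efrom[e] = from[e] - 1;
    eto[e] = to[e] - 1;
    ew[e] = weight[e];
  }

  int cn = n;
  for (int level = 0; level < 64; ++level) {
    const size_t ne = efrom.size();
    // CSR adjacency (both directions; self loops stored once)
    std::vector<int> deg(cn + 1, 0);
    for (size_t e = 0; e < ne; ++e) {
      deg[efrom[e] + 1]++;
      if (eto[e] != efrom[e]) deg[eto[e] + 1]++;
    }
    for (int i = 0; i < cn; ++i) deg[i + 1] += deg[i];
    std::vector<int> adj_to(deg[cn]);
    std::vector<double> adj_w(deg[cn]);
    {
      std::vector<int> pos(deg.begin(), deg.end() - 1);
      for (size_t e = 0; e < ne; ++e) {
        adj_to[pos[efrom[e]]] = eto[e];
        adj_w[pos[efrom[e]]++] = ew[e];
        if (eto[e] != efrom[e]) {
          adj_to[pos[eto[e]]] = efrom[e];
          adj_w[pos[eto[e]]++] = ew[e];
        }
      }
    }
    double m = 0.0;
    std::vector<double> k(cn, 0.0);   // weighted degree, self loops twice
    for (size_t e = 0; e < ne; ++e) {
      m += ew[e];
      k[efrom[e]] += ew[e];
      k[eto[e]] += ew[e];
    }
    if (m <= 0) break;

    std::vector<int> comm(cn);
    std::vector<double> tot(k);
    for (int i = 0; i < cn; ++i) comm[i] = i;

    // local moving phase
    std::vector<double> ncw(cn, 0.0);
    std::vector<int> touched;
    touched.reserve(64);
    bool any_move = false;
    for (int pass = 0; pass < 100; ++pass) {
      bool moved = false;
      for (int i = 0; i < cn; ++i) {
        touched.clear();
        for (int a = deg[i]; a < deg[i + 1]; ++a) {
          const int j = adj_to[a];
          if (j == i) continue;   // self loop moves with i: constant term
          const int c = comm[j];
          if (ncw[c] == 0.0) touched.push_back(c);
          ncw[c] += adj_w[a];
        }
        const int c_old = comm[i];
        tot[c_old] -= k[i];
        // gain of joining c relative to staying alone: w_ic - tot_c*k_i/2m
        double best_gain = ncw[c_old] - tot[c_old] * k[i] / (2.0 * m);
        int best_c = c_old;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int c = touched[t];
          const double gain = ncw[c] - tot[c] * k[i] / (2.0 * m);
          if (gain > best_gain + eps ||
              (gain > best_gain - eps && c < best_c)) {
            best_gain = gain;
            best_c = c;
          }
        }
        tot[best_c] += k[i];
        if (best_c != c_old) {
          comm[i] = best_c;
          moved = true;
          any_move = true;
        }
        for (size_t t = 0; t < touched.size(); ++t) ncw[touched[t]] = 0.0;
        ncw[c_old] = 0.0;
      }
      if (!moved) break;
    }

    // relabel communities contiguously, ordered by their smallest member
    std::vector<int> newlab(cn, -1);
    int kcomm = 0;
    for (int i = 0; i < cn; ++i) {
      if (newlab[comm[i]] < 0) newlab[comm[i]] = kcomm++;
    }
    for (int i = 0; i < n; ++i) orig2cur[i] = newlab[comm[orig2cur[i]]];
    if (kcomm == cn || !any_move) break;

    // aggregate the graph
    std::unordered_map<uint64_t, double> agg;
    agg.reserve(ne / 4 + 8);
    for (size_t e = 0; e < ne; ++e) {
      int a = newlab[comm[efrom[e]]];
      int b = newlab[comm[eto[e]]];
      if (a > b) std::swap(a, b);
      agg[(static_cast<uint64_t>(a) << 32) | static_cast<uint32_t>(b)] += ew[e];
    }
    efrom.clear(); eto.clear(); ew.clear();
    efrom.reserve(agg.size()); eto.reserve(agg.size()); ew.reserve(agg.size());
    for (std::unordered_map<uint64_t, double>::const_iterator it = agg.begin();
         it != agg.end(); ++it) {
      efrom.push_back(static_cast<int>(it->first >> 32));
      eto.push_back(static_cast<int>(it->first & 0xffffffffu));
      ew.push_back(it->second);
    }
    cn = kcomm;
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = orig2cur[i] + 1;
  return out;
}
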