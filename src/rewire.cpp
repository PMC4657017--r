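#include <Rcpp.h>
using namespace Rcpp;

// Double-edge swaps preserving degrees within one sub-network.
// si, ti: 1-based endpoint indices (source side / target side); for an
// undirected sub-network both sides index the same node set. Proposals
// creating self-loops or duplicate edges are rejected, so the edge set
// stays a simple graph with the input degree sequences. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List rewire_edges_impl(IntegerVector si, IntegerVector ti, int n_s, int n_t,
                       bool undirected, int n_try) {
  const int n_e = si.size();
  std::vector<int> s(si.begin(), si.end()), t(ti.begin(), ti.end());
  std::vector<bool> present(static_cast<size_t>(n_s) * n_t, false);

  auto key = [&](int a, int b) -> size_t {
    if (undirected) {
      int lo = a < b ? a : b, hi = a < b ? b : a;
      return static_cast<size_t>(lo - 1) * n_t + (hi - 1);
    }
    return static_cast<size_t>(a - 1) * n_t + (b - 1);
  };

  for (int e = 0; e < n_e; ++e) present[key(s[e], t[e])] = true;

  for (int it = 0; it < n_try; ++it) {
    int i = static_cast<int>(unif_rand() * n_e);
    int j = static_cast<int>(unif_rand() * n_e);
    if (i >= n_e) i = n_e - 1;
    if (j >= n_e) j = n_e - 1;
    if (i == j) continue;
    int a1 = s[i], b1 = t[i], a2 = s[j], b2 = t[j];
    if (undirected) {
      // stored orientation is arbitrary: flip each edge with prob 1/2
      if (unif_rand() < 0.5) std::swap(a1, b1);
      if (unif_rand() < 0.5) std::swap(a2, b2);
      if (a1 == b2 || a2 == b1) continue; // self-loop
    }
    size_t k1 = key(a1, b2), k2 = key(a2, b1);
    if (k1 == k2 || present[k1] || present[k2]) continue;
    present[key(s[i], t[i])] = false;
    present[key(s[j], t[j])] = false;
    present[k1] = true;
    present[k2] = true;
    s[i] = a1; t[i] = b2;
    s[j] = a2; t[j] = b1;
  }

  return List::create(_["si"] = IntegerVector(s.begin(), s.end()),
                      _["ti"] = IntegerVector(t.begin(), t.end()));
}
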