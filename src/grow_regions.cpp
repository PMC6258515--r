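#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Uniform integer on [0, m) from R's RNG stream.
static inline int runif_int(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

// Seed-based region growing on a contiguity graph. `nbr` holds 0-based
// neighbour ids per area. k distinct seed areas are drawn uniformly; then,
// while unassigned areas remain, one unassigned area adjacent to at least one
// grown region is picked uniformly at random and joined to a uniformly
// random adjacent region. Regions stay connected by construction. Uses R's
// RNG, so reproducibility follows from set.seed() in the caller.
// [[Rcpp::export]]
IntegerVector grow_regions_cpp(List nbr, int k) {
  const int n = nbr.size();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbr[i];
    adj[i].assign(v.begin(), v.end());
  }
  std::vector<int> lab(n, -1);

  // partial Fisher-Yates draw of k distinct seeds
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int j = 0; j < k; ++j) {
    int idx = j + runif_int(n - j);
    std::swap(pool[j], pool[idx]);
    lab[pool[j]] = j;
  }

  // frontier: unassigned areas adjacent to >= 1 assigned area
  std::vector<int> frontier;
  frontier.reserve(n);
  std::vector<int> fpos(n, -1);
  for (int j = 0; j < k; ++j) {
    for (int u : adj[pool[j]]) {
      if (lab[u] < 0 && fpos[u] < 0) {
        fpos[u] = frontier.size();
        frontier.push_back(u);
      }
    }
  }

  int assigned = k;
  std::vector<int> regs;
  regs.reserve(8);
  while (!frontier.empty()) {
    int fi = runif_int((int)frontier.size());
    int v = frontier[fi];
    regs.clear();
    for (int u : adj[v]) {
      int r = lab[u];
      if (r >= 0) {
        bool seen = false;
        for (int q : regs) if (q == r) { seen = true; break; }
        if (!seen) regs.push_back(r);
      }
    }
    lab[v] = regs[runif_int((int)regs.size())];
    ++assigned;
    int last = frontier.back();
    frontier[fi] = last;
    fpos[last] = fi;
    frontier.pop_back();
    fpos[v] = -1;
    for (int u : adj[v]) {
      if (lab[u] < 0 && fpos[u] < 0) {
        fpos[u] = frontier.size();
        frontier.push_back(u);
      }
    }
  }
  if (assigned != n) stop("region growing stalled; the graph is disconnected");
  return IntegerVector(lab.begin(), lab.end());
}
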