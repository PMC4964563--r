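#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Kernels for the foundation phase of the colony-founding model. Both use
// R's RNG stream (unif_rand via RNGScope), so results are reproducible from
// set.seed() on the R side and no state leaks between calls.

static inline int wrap(int v, int n) {
  v %= n;
  return v < 0 ? v + n : v;
}

// One full clustering pass: queens, visited in the order given, each move to
// the suitable cell within the clustering radius holding the most OTHER
// queens at the moment of the move. Candidate offsets (including (0,0)) are
// precomputed on the R side for the radius in use. Ties among cells with a
// positive count are broken uniformly at random; a tie at count zero keeps
// the queen where she is. Cell indices are 0-based, row-major (r * n + c).
//
// [[Rcpp::export]]
IntegerVector cluster_pass_cpp(IntegerVector cell, LogicalVector suitable,
                               int n_side, IntegerVector off_dr,
                               IntegerVector off_dc, IntegerVector order) {
  int m = cell.size();
  int k = off_dr.size();
  std::vector<int> counts((size_t)n_side * n_side, 0);
  for (int i = 0; i < m; ++i) counts[cell[i]]++;

  IntegerVector out = clone(cell);
  std::vector<int> best;
  best.reserve(k);

  for (int oi = 0; oi < m; ++oi) {
    int i = order[oi];            // 0-based queen index
    int cur = out[i];
    int r0 = cur / n_side, c0 = cur % n_side;
    counts[cur]--;                // she counts others, not herself

    int best_count = -1;
    best.clear();
    for (int j = 0; j < k; ++j) {
      int idx = wrap(r0 + off_dr[j], n_side) * n_side + wrap(c0 + off_dc[j], n_side);
      if (!suitable[idx]) continue;
      int cnt = counts[idx];
      if (cnt > best_count) {
        best_count = cnt;
        best.clear();
        best.push_back(idx);
      } else if (cnt == best_count) {
        best.push_back(idx);
      }
    }

    int dest;
    if (best_count <= 0 || best.empty()) {
      dest = cur;                 // nobody in reach (or no candidate): stay
    } else if (best.size() == 1) {
      dest = best[0];
    } else {
      int j = (int)(unif_rand() * best.size());
      if (j >= (int)best.size()) j = (int)best.size() - 1;
      dest = best[j];
    }
    out[i] = dest;
    counts[dest]++;
  }
  return out;
}

// Fight resolution within one cell. Every unordered pair of queens is
// visited once, in uniformly random order; pairs with a dead member are
// skipped. A fight occurs if at least one aggressive, living member of the
// pair initiates (independent draws at p_init each). Exactly one queen dies
// per fight: 50/50 between two aggressors; between an aggressor and a
// cooperator the aggressor dies with p_df, otherwise the cooperator dies.
// Returns the alive mask. The last living queen can never be paired with
// another living queen, so at least one always survives.
//
// [[Rcpp::export]]
LogicalVector fight_group_cpp(LogicalVector aggressive, double p_init,
                              double p_df) {
  int n = aggressive.size();
  LogicalVector alive(n, true);
  if (n < 2) return alive;

  std::vector<std::pair<int, int> > pairs;
  pairs.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pairs.push_back(std::make_pair(i, j));

  // Fisher-Yates on the pair list, driven by R's RNG
  for (int i = (int)pairs.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(pairs[i], pairs[j]);
  }

  for (size_t p = 0; p < pairs.size(); ++p) {
    int a = pairs[p].first, b = pairs[p].second;
    if (!alive[a] || !alive[b]) continue;
    bool init_a = aggressive[a] && unif_rand() < p_init;
    bool init_b = aggressive[b] && unif_rand() < p_init;
    if (!init_a && !init_b) continue;
    if (aggressive[a] && aggressive[b]) {
      if (unif_rand() < 0.5) alive[a] = false; else alive[b] = false;
    } else if (aggressive[a]) {
      if (unif_rand() < p_df) alive[a] = false; else alive[b] = false;
    } else {
      if (unif_rand() < p_df) alive[b] = false; else alive[a] = false;
    }
  }
  return alive;
}
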