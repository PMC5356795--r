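#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving rewiring null for the NOD statistic on a bipartite
// directed miRNA->gene graph. Each permutation starts from the observed
// edge set and applies checkerboard (double-edge) swaps:
//   (m1,g1),(m2,g2) -> (m1,g2),(m2,g1)
// rejected when it would duplicate an existing edge, so every permuted
// graph is simple with the exact observed degree sequences. Uses R's RNG,
// so results are reproducible under set.seed().
//
// mirna, gene: 0-based edge endpoints; focal: 0-based miRNA indices for
// which NOD* is recorded. Returns an n_perm x length(focal) matrix of
// permuted NOD values.
// [[Rcpp::export]]
IntegerMatrix nod_permutation_counts(IntegerVector mirna, IntegerVector gene,
                                     int n_mirna, int n_gene,
                                     IntegerVector focal, int n_perm,
                                     double swap_factor) {
  const int ne = mirna.size();
  const int nf = focal.size();
  IntegerMatrix out(n_perm, nf);
  if (ne == 0 || nf == 0 || n_perm == 0) return out;

  std::vector<int> focal_col(n_mirna, -1);
  for (int j = 0; j < nf; ++j) focal_col[focal[j]] = j;

  const long long attempts = (long long)(swap_factor * ne) + 1;
  std::vector<int> m(ne), g(ne);
  std::vector<int> indeg(n_gene);
  const long long G = n_gene;
  // edge-membership structure: dense byte matrix when it fits (fast, no
  // hashing), hash set otherwise
  const bool dense = (double)n_mirna * (double)n_gene <= 4e7;
  std::vector<char> mat;
  if (dense) mat.assign((size_t)n_mirna * n_gene, 0);
  std::unordered_set<long long> present;
  if (!dense) present.reserve(ne * 2);

  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < ne; ++i) { m[i] = mirna[i]; g[i] = gene[i]; }
    if (dense) {
      if (p > 0) std::fill(mat.begin(), mat.end(), 0);
      for (int i = 0; i < ne; ++i) mat[(size_t)m[i] * G + g[i]] = 1;
    } else {
      present.clear();
      for (int i = 0; i < ne; ++i) present.insert((long long)m[i] * G + g[i]);
    }

    for (long long s = 0; s < attempts; ++s) {
      int i = (int)(unif_rand() * ne); if (i >= ne) i = ne - 1;
      int j = (int)(unif_rand() * ne); if (j >= ne) j = ne - 1;
      if (i == j) continue;
      if (m[i] == m[j] || g[i] == g[j]) continue;
      long long new_i = (long long)m[i] * G + g[j];
      long long new_j = (long long)m[j] * G + g[i];
      long long old_i = (long long)m[i] * G + g[i];
      long long old_j = (long long)m[j] * G + g[j];
      if (dense) {
        if (mat[new_i] || mat[new_j]) continue;
        mat[old_i] = 0; mat[old_j] = 0;
        mat[new_i] = 1; mat[new_j] = 1;
      } else {
        if (present.count(new_i) || present.count(new_j)) continue;
        present.erase(old_i);
        present.erase(old_j);
        present.insert(new_i);
        present.insert(new_j);
      }
      int tmp = g[i]; g[i] = g[j]; g[j] = tmp;
    }

    std::fill(indeg.begin(), indeg.end(), 0);
    for (int i = 0; i < ne; ++i) ++indeg[g[i]];
    for (int i = 0; i < ne; ++i) {
      if (indeg[g[i]] == 1) {
        int col = focal_col[m[i]];
        if (col >= 0) ++out(p, col);
      }
    }
  }
  return out;
}
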