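#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xorshift64* PRNG: layout must be reproducible from a scalar seed and
// independent of R's RNG stream (the caller owns R's stream).
static inline uint64_t xorshift64(uint64_t &state) {
  state ^= state >> 12;
  state ^= state << 25;
  state ^= state >> 27;
  return state * 2685821657736338717ULL;
}

static inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// Stochastic gradient layout of the fuzzy topological representation,
// following the sampling schedule of the reference UMAP optimizer:
// each 1-simplex (head[e], tail[e]) is sampled once every
// epochs_per_sample[e] epochs; every positive update is followed by
// `neg_rate` repulsive updates against uniformly drawn vertices.
// [[Rcpp::export]]
NumericMatrix umap_layout_cpp(NumericMatrix embedding,
                              IntegerVector head,
                              IntegerVector tail,
                              NumericVector epochs_per_sample,
                              int n_epochs,
                              double initial_alpha,
                              double a,
                              double b,
                              double neg_rate,
                              double seed) {
  NumericMatrix emb = clone(embedding);
  const int n_vertices = emb.nrow();
  const int dim = emb.ncol();
  const int n_edges = head.size();

  std::vector<double> epoch_of_next_sample(n_edges);
  std::vector<double> epochs_per_negative_sample(n_edges);
  std::vector<double> epoch_of_next_negative_sample(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    epoch_of_next_sample[e] = epochs_per_sample[e];
    epochs_per_negative_sample[e] = epochs_per_sample[e] / neg_rate;
    epoch_of_next_negative_sample[e] = epochs_per_negative_sample[e];
  }

  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  for (int n = 1; n <= n_epochs; ++n) {
    double alpha = initial_alpha * (1.0 - (double)(n - 1) / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (epoch_of_next_sample[e] > n) continue;
      int i = head[e], j = tail[e];

      // attractive move along the edge; both endpoints move
      double dist2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double diff = emb(i, d) - emb(j, d);
        dist2 += diff * diff;
      }
      double grad_coeff = 0.0;
      if (dist2 > 0.0) {
        grad_coeff = -2.0 * a * b * std::pow(dist2, b - 1.0);
        grad_coeff /= a * std::pow(dist2, b) + 1.0;
      }
      for (int d = 0; d < dim; ++d) {
        double g = clip4(grad_coeff * (emb(i, d) - emb(j, d)));
        emb(i, d) += alpha * g;
        emb(j, d) -= alpha * g;
      }
      epoch_of_next_sample[e] += epochs_per_sample[e];

      // repulsive moves against random vertices; only the head moves
      int n_neg = (int)((n - epoch_of_next_negative_sample[e]) /
                        epochs_per_negative_sample[e]);
      for (int p = 0; p < n_neg; ++p) {
        int k = (int)(xorshift64(rng) % (uint64_t)n_vertices);
        if (k == i) continue;
        double d2 = 0.0;
        for (int d = 0; d < dim; ++d) {
          double diff = emb(i, d) - emb(k, d);
          d2 += diff * diff;
        }
        double gc;
        if (d2 > 0.0) {
          gc = 2.0 * b;
          gc /= (0.001 + d2) * (a * std::pow(d2, b) + 1.0);
        } else {
          gc = 0.0;
        }
        for (int d = 0; d < dim; ++d) {
          double g = (gc > 0.0) ? clip4(gc * (emb(i, d) - emb(k, d))) : 4.0;
          emb(i, d) += alpha * g;
        }
      }
      epoch_of_next_negative_sample[e] += n_neg * epochs_per_negative_sample[e];
    }
  }
  return emb;
}

// Prim's algorithm on a dense symmetric distance matrix; returns the
// (n-1) x 3 MST edge list (from, to, weight), 1-based indices.  Used on
// mutual-reachability distances where n is at most a few thousand.
// [[Rcpp::export]]
NumericMatrix prim_mst_cpp(NumericMatrix d) {
  const int n = d.nrow();
  NumericMatrix edges(n - 1, 3);
  std::vector<bool> in_tree(n, false);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> parent(n, -1);
  in_tree[0] = true;
  for (int j = 1; j < n; ++j) { best[j] = d(0, j); parent[j] = 0; }
  for (int it = 0; it < n - 1; ++it) {
    int v = -1;
    double bv = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && best[j] < bv) { bv = best[j]; v = j; }
    in_tree[v] = true;
    edges(it, 0) = parent[v] + 1;
    edges(it, 1) = v + 1;
    edges(it, 2) = bv;
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && d(v, j) < best[j]) { best[j] = d(v, j); parent[j] = v; }
  }
  return edges;
}
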