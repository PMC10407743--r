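// Random-walk network embedding: uniform (p = q = 1) walks over an
// undirected graph followed by skip-gram with negative sampling, trained
// with plain SGD in one pass. Single-threaded and fully seeded so repeated
// runs are bit-identical.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// adj: flat 0-based neighbor array, offsets: size n+1 (CSR layout).
// [[Rcpp::export]]
NumericMatrix node2vec_embed(IntegerVector offsets, IntegerVector adj,
                             int dim, int walks_per_node, int walk_len,
                             int window, int negatives, double lr_init,
                             int seed) {
  const int n = offsets.size() - 1;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  // Walk corpus. Nodes with no neighbors produce no walks (callers drop
  // isolated nodes beforehand).
  std::vector<int> corpus;
  corpus.reserve(static_cast<size_t>(n) * walks_per_node * walk_len);
  std::vector<int> walk_starts;
  std::vector<long long> freq(n, 0);
  for (int w = 0; w < walks_per_node; ++w) {
    for (int v = 0; v < n; ++v) {
      if (offsets[v + 1] == offsets[v]) continue;
      walk_starts.push_back(static_cast<int>(corpus.size()));
      int cur = v;
      for (int s = 0; s < walk_len; ++s) {
        corpus.push_back(cur);
        ++freq[cur];
        int deg = offsets[cur + 1] - offsets[cur];
        if (deg == 0) break;
        std::uniform_int_distribution<int> pick(0, deg - 1);
        cur = adj[offsets[cur] + pick(rng)];
      }
    }
  }
  walk_starts.push_back(static_cast<int>(corpus.size()));

  // Unigram^0.75 negative-sampling table.
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(n);
    for (int v = 0; v < n; ++v) {
      pw[v] = std::pow(static_cast<double>(freq[v]), 0.75);
      z += pw[v];
    }
    if (z <= 0.0) stop("embedding: graph produced an empty walk corpus");
    int v = 0;
    double cum = pw[0] / z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if (static_cast<double>(i + 1) / table_size > cum && v < n - 1) {
        ++v;
        cum += pw[v] / z;
      }
    }
  }

  // Parameter init as in word2vec: input vectors uniform in
  // [-0.5/dim, 0.5/dim], output vectors zero.
  std::vector<float> syn0(static_cast<size_t>(n) * dim);
  std::vector<float> syn1(static_cast<size_t>(n) * dim, 0.0f);
  std::uniform_real_distribution<double> unif(-0.5, 0.5);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = static_cast<float>(unif(rng) / dim);
  }

  const double total_words = static_cast<double>(corpus.size());
  double processed = 0.0;
  std::vector<float> grad(dim);
  std::uniform_int_distribution<int> wnd(1, window);
  std::uniform_int_distribution<int> tbl(0, table_size - 1);

  const size_t n_walks = walk_starts.size() - 1;
  for (size_t wi = 0; wi < n_walks; ++wi) {
    int lo = walk_starts[wi], hi = walk_starts[wi + 1];
    for (int i = lo; i < hi; ++i) {
      double lr = lr_init * (1.0 - processed / (total_words + 1.0));
      if (lr < lr_init * 1e-4) lr = lr_init * 1e-4;
      processed += 1.0;
      int b = wnd(rng);
      for (int j = i - b; j <= i + b; ++j) {
        if (j < lo || j >= hi || j == i) continue;
        int center = corpus[j];
        int target = corpus[i];
        float* v_in = &syn0[static_cast<size_t>(center) * dim];
        std::fill(grad.begin(), grad.end(), 0.0f);
        for (int d = 0; d <= negatives; ++d) {
          int tgt;
          double label;
          if (d == 0) {
            tgt = target;
            label = 1.0;
          } else {
            tgt = table[tbl(rng)];
            if (tgt == target) continue;
            label = 0.0;
          }
          float* v_out = &syn1[static_cast<size_t>(tgt) * dim];
          double dot = 0.0;
          for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
          double g = (label - sigmoid_clip(dot)) * lr;
          for (int k = 0; k < dim; ++k) {
            grad[k] += static_cast<float>(g) * v_out[k];
            v_out[k] += static_cast<float>(g) * v_in[k];
          }
        }
        for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
      }
    }
  }

  NumericMatrix out(n, dim);
  for (int v = 0; v < n; ++v) {
    for (int k = 0; k < dim; ++k) {
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
    }
  }
  return out;
}
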