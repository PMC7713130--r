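#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// adjacency is passed CSR-style (0-based, column-sorted); symmetric graphs
// only, so rows == columns of the dgCMatrix slots.

static inline bool is_neighbor(const int *indices, int lo, int hi, int x) {
  return std::binary_search(indices + lo, indices + hi, x);
}

// second-order biased random walks: from (prev t, cur v) the next node x is
// drawn with unnormalized weight 1/p if x == t, 1 if x ~ t, else 1/q
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector indptr, IntegerVector indices,
                        double p, double q, int walk_length,
                        int walks_per_node, int seed) {
  const int n = indptr.size() - 1;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> starts;
  for (int v = 0; v < n; ++v)
    if (indptr[v + 1] > indptr[v]) starts.push_back(v);

  List out(starts.size() * (size_t)walks_per_node);
  size_t w_idx = 0;
  std::vector<double> wts;
  std::vector<int> walk(walk_length);
  for (int rep = 0; rep < walks_per_node; ++rep) {
    // shuffle start order per pass, as walk-based embedders do
    std::shuffle(starts.begin(), starts.end(), rng);
    for (size_t s = 0; s < starts.size(); ++s) {
      int cur = starts[s];
      int prev = -1;
      walk[0] = cur;
      int len = 1;
      for (int step = 1; step < walk_length; ++step) {
        int lo = indptr[cur], hi = indptr[cur + 1];
        int deg = hi - lo;
        if (deg == 0) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          std::uniform_int_distribution<int> pick(0, deg - 1);
          nxt = indices[lo + pick(rng)];
        } else {
          wts.resize(deg);
          int plo = indptr[prev], phi = indptr[prev + 1];
          for (int e = 0; e < deg; ++e) {
            int x = indices[lo + e];
            if (x == prev) wts[e] = 1.0 / p;
            else if (is_neighbor(&indices[0], plo, phi, x)) wts[e] = 1.0;
            else wts[e] = 1.0 / q;
          }
          std::discrete_distribution<int> pick(wts.begin(), wts.end());
          nxt = indices[lo + pick(rng)];
        }
        walk[step] = nxt;
        prev = cur;
        cur = nxt;
        ++len;
      }
      IntegerVector wv(len);
      for (int t = 0; t < len; ++t) wv[t] = walk[t] + 1; // back to 1-based
      out[w_idx++] = wv;
    }
  }
  if (w_idx < (size_t)out.size()) out.erase(w_idx, out.size());
  return out;
}

#define SIGMOID_BOUND 6.0
#define SIGMOID_TABLE 1024

// skip-gram with negative sampling over a walk corpus. tokens holds all
// walks concatenated (1-based node ids), lens their lengths. Returns the
// N x dim input-vector matrix. epochs == 0 returns the seeded uniform
// initialization untouched. Single-threaded by design for reproducibility;
// single-precision accumulators and a sigmoid lookup table, as in the
// reference word2vec implementation.
// [[Rcpp::export]]
NumericMatrix cpp_train_skipgram(IntegerVector tokens, IntegerVector lens,
                                 int n_nodes, int dim, int window,
                                 int epochs, int negative, double alpha,
                                 int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<float> W((size_t)n_nodes * dim), C((size_t)n_nodes * dim, 0.0f);
  {
    std::uniform_real_distribution<double> u(-0.5 / dim, 0.5 / dim);
    for (size_t i = 0; i < W.size(); ++i) W[i] = (float)u(rng);
  }

  float sig[SIGMOID_TABLE];
  for (int i = 0; i < SIGMOID_TABLE; ++i) {
    double x = (2.0 * i / SIGMOID_TABLE - 1.0) * SIGMOID_BOUND;
    sig[i] = (float)(1.0 / (1.0 + std::exp(-x)));
  }

  // unigram^0.75 negative-sampling distribution over corpus frequencies,
  // realized as a dense sampling table for O(1) draws
  std::vector<double> freq(n_nodes, 0.0);
  for (int t = 0; t < tokens.size(); ++t) freq[tokens[t] - 1] += 1.0;
  const int TBL = 1 << 20;
  std::vector<int> unigram(TBL);
  {
    double z = 0.0;
    for (int v = 0; v < n_nodes; ++v) z += std::pow(freq[v], 0.75);
    int v = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int i = 0; i < TBL; ++i) {
      unigram[i] = v;
      if ((double)(i + 1) / TBL > cum && v < n_nodes - 1) {
        ++v;
        cum += std::pow(freq[v], 0.75) / z;
      }
    }
  }
  std::uniform_int_distribution<int> tbl_dist(0, TBL - 1);
  std::uniform_int_distribution<int> win_dist(1, std::max(1, window));

  const double total = std::max(1.0, (double)tokens.size() * epochs);
  double processed = 0.0;
  std::vector<float> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    int off = 0;
    for (int wi = 0; wi < lens.size(); ++wi) {
      int L = lens[wi];
      for (int i = 0; i < L; ++i) {
        processed += 1.0;
        float lr = (float)(alpha * std::max(1e-4, 1.0 - processed / total));
        int center = tokens[off + i] - 1;
        int b = win_dist(rng);
        int jlo = std::max(0, i - b), jhi = std::min(L - 1, i + b);
        float *wc = &W[(size_t)center * dim];
        for (int j = jlo; j <= jhi; ++j) {
          if (j == i) continue;
          int ctx = tokens[off + j] - 1;
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int m = 0; m <= negative; ++m) {
            int target;
            float label;
            if (m == 0) { target = ctx; label = 1.0f; }
            else {
              target = unigram[tbl_dist(rng)];
              if (target == ctx) continue;
              label = 0.0f;
            }
            float *ct = &C[(size_t)target * dim];
            float f = 0.0f;
            for (int d = 0; d < dim; ++d) f += wc[d] * ct[d];
            float s;
            if (f > SIGMOID_BOUND) s = 1.0f;
            else if (f < -SIGMOID_BOUND) s = 0.0f;
            else {
              int si = (int)((f / SIGMOID_BOUND + 1.0f) *
                             (SIGMOID_TABLE / 2));
              if (si >= SIGMOID_TABLE) si = SIGMOID_TABLE - 1;
              s = sig[si];
            }
            float g = (label - s) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * ct[d];
              ct[d] += g * wc[d];
            }
          }
          for (int d = 0; d < dim; ++d) wc[d] += grad[d];
        }
      }
      off += L;
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = W[(size_t)v * dim + d];
  return out;
}
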