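// Skip-gram with negative sampling over random-walk corpora.
//
// Single-threaded SGD in corpus order with its own xorshift RNG, so a fixed
// seed reproduces the embedding bit for bit regardless of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t& s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double runif01(uint64_t& s) {
  return (double)(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
List sg_train_cpp(List walks, int n_nodes, int d, int window, int epochs,
                  int negatives, double alpha, int seed) {
  const int n_walks = walks.size();
  std::vector<std::vector<int>> corpus(n_walks);
  std::vector<double> counts(n_nodes, 0.0);
  long long total_pairs = 0;
  for (int i = 0; i < n_walks; ++i) {
    IntegerVector w = walks[i];
    std::vector<int>& cw = corpus[i];
    cw.reserve(w.size());
    for (int j = 0; j < w.size(); ++j) {
      int node = w[j] - 1;  // R indices are 1-based
      if (node < 0 || node >= n_nodes) stop("walk node index out of range");
      cw.push_back(node);
      counts[node] += 1.0;
    }
    int len = (int)cw.size();
    for (int j = 0; j < len; ++j) {
      int lo = j - window < 0 ? 0 : j - window;
      int hi = j + window >= len ? len - 1 : j + window;
      total_pairs += hi - lo;  // contexts excluding the centre itself
    }
  }
  if (total_pairs == 0) stop("walk corpus contains no context pairs");

  // unigram^{3/4} table for negative sampling
  std::vector<double> cum(n_nodes, 0.0);
  double z = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    z += std::pow(counts[v], 0.75);
    cum[v] = z;
  }
  if (z <= 0.0) stop("empty corpus");

  uint64_t rng = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
  for (int burn = 0; burn < 8; ++burn) xorshift64(rng);

  std::vector<double> syn0((size_t)n_nodes * d);
  std::vector<double> syn1((size_t)n_nodes * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (runif01(rng) - 0.5) / d;
  }
  std::vector<long long> centre_pairs(n_nodes, 0);
  std::vector<double> grad(d);

  const double min_alpha_frac = 1e-4;
  long long processed = 0;
  // expected pair count under the reduced window, for the lr schedule
  const long long total =
      (long long)((double)total_pairs * (window + 1) / (2.0 * window)) *
      (long long)epochs;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      const std::vector<int>& cw = corpus[i];
      const int len = (int)cw.size();
      for (int j = 0; j < len; ++j) {
        const int centre = cw[j];
        // reduced window as in canonical word2vec: effective size 1..window
        const int b = 1 + (int)(runif01(rng) * window);
        const int lo = j - b < 0 ? 0 : j - b;
        const int hi = j + b >= len ? len - 1 : j + b;
        for (int c = lo; c <= hi; ++c) {
          if (c == j) continue;
          const int ctx = cw[c];
          double lr = alpha *
            std::max(1.0 - (double)processed / (double)(total + 1),
                     min_alpha_frac);
          if (lr < alpha * min_alpha_frac) lr = alpha * min_alpha_frac;
          ++processed;
          ++centre_pairs[centre];
          double* v_in = &syn0[(size_t)centre * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = runif01(rng) * z;
              int tlo = 0, thi = n_nodes - 1;
              while (tlo < thi) {
                int mid = (tlo + thi) / 2;
                if (cum[mid] < u) tlo = mid + 1; else thi = mid;
              }
              target = tlo;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * d];
            double f = 0.0;
            for (int q = 0; q < d; ++q) f += v_in[q] * v_out[q];
            const double g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
            for (int q = 0; q < d; ++q) {
              grad[q] += g * v_out[q];
              v_out[q] += g * v_in[q];
            }
          }
          for (int q = 0; q < d; ++q) v_in[q] += grad[q];
        }
      }
    }
  }

  NumericMatrix emb(n_nodes, d);
  for (int v = 0; v < n_nodes; ++v) {
    for (int q = 0; q < d; ++q) emb(v, q) = syn0[(size_t)v * d + q];
  }
  IntegerVector np(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    np[v] = (int)std::min<long long>(centre_pairs[v], INT_MAX);
  }
  return List::create(_["embedding"] = emb, _["centre_pairs"] = np);
}
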