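// Seeded, single-threaded implementations of the two graph-representation
// learners: node2vec (second-order biased random walks + skip-gram with
// negative sampling) and LINE (first/second-order proximity, edge-sampling
// SGD). A private mt19937 stream keeps every run bit-reproducible for a
// given seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // uniform in [0, 1); derived from raw draws so behaviour is identical
  // across standard-library implementations
  double unif() { return gen() * (1.0 / 4294967296.0); }
  int unif_int(int n) { return std::min<int>(n - 1, (int)(unif() * n)); }
};

// binary search a cumulative-weight table; returns index in [0, n)
int sample_cum(const std::vector<double>& cum, Rng& rng) {
  double r = rng.unif() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
}

inline double sigmoidd(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List cpp_node2vec_walks(List adj, List wts, double p, double q,
                        int walks_per_node, int walk_length, int seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<double>> nw(n);
  std::vector<std::vector<double>> cum_first(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    NumericVector w = wts[i];
    nb[i].assign(a.begin(), a.end());     // 0-based, sorted ascending
    nw[i].assign(w.begin(), w.end());
    double acc = 0.0;
    cum_first[i].resize(a.size());
    for (int j = 0; j < (int)a.size(); ++j) {
      acc += nw[i][j];
      cum_first[i][j] = acc;
    }
  }
  Rng rng((uint32_t)seed);
  List out(n * walks_per_node);
  std::vector<double> cum;
  int k = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(v);
      if (!nb[v].empty() && walk_length > 1) {
        int cur = nb[v][sample_cum(cum_first[v], rng)];
        walk.push_back(cur);
        int prev = v;
        while ((int)walk.size() < walk_length) {
          const std::vector<int>& nn = nb[cur];
          if (nn.empty()) break;
          const std::vector<double>& ww = nw[cur];
          cum.resize(nn.size());
          const std::vector<int>& pn = nb[prev];
          double acc = 0.0;
          for (size_t j = 0; j < nn.size(); ++j) {
            int x = nn[j];
            double bias;
            if (x == prev) {
              bias = 1.0 / p;                 // return to the previous node
            } else if (std::binary_search(pn.begin(), pn.end(), x)) {
              bias = 1.0;                     // distance 1 from prev
            } else {
              bias = 1.0 / q;                 // distance 2: outward move
            }
            acc += ww[j] * bias;
            cum[j] = acc;
          }
          int nxt = nn[sample_cum(cum, rng)];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      IntegerVector wv(walk.size());
      for (size_t j = 0; j < walk.size(); ++j) wv[j] = walk[j] + 1;  // 1-based
      out[k++] = wv;
    }
  }
  return out;
}

// One-step transition distribution of the second-order walk, for testing.
// [[Rcpp::export]]
NumericVector cpp_node2vec_step_probs(IntegerVector nbr, NumericVector w,
                                      IntegerVector prev_nbr, int prev,
                                      double p, double q) {
  int m = nbr.size();
  NumericVector out(m);
  std::vector<int> pn(prev_nbr.begin(), prev_nbr.end());
  std::sort(pn.begin(), pn.end());
  double tot = 0.0;
  for (int j = 0; j < m; ++j) {
    double bias;
    if (nbr[j] == prev) bias = 1.0 / p;
    else if (std::binary_search(pn.begin(), pn.end(), (int)nbr[j])) bias = 1.0;
    else bias = 1.0 / q;
    out[j] = w[j] * bias;
    tot += out[j];
  }
  for (int j = 0; j < m; ++j) out[j] /= tot;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, int n_vocab, int dim, int window,
                             int negative, int epochs, double alpha0,
                             int seed) {
  Rng rng((uint32_t)seed);
  // unigram^0.75 noise table as cumulative weights
  std::vector<double> freq(n_vocab, 0.0);
  long long total_tokens = 0;
  int n_walks = walks.size();
  for (int i = 0; i < n_walks; ++i) {
    IntegerVector w = walks[i];
    total_tokens += w.size();
    for (int j = 0; j < w.size(); ++j) freq[w[j] - 1] += 1.0;
  }
  std::vector<double> noise_cum(n_vocab);
  double acc = 0.0;
  for (int i = 0; i < n_vocab; ++i) {
    acc += std::pow(freq[i], 0.75);
    noise_cum[i] = acc;
  }
  // row-major flat buffers: node vectors are contiguous in memory
  std::vector<double> syn0((size_t)n_vocab * dim);
  std::vector<double> syn1((size_t)n_vocab * dim, 0.0);
  for (int i = 0; i < n_vocab; ++i)
    for (int d = 0; d < dim; ++d)
      syn0[(size_t)i * dim + d] = (rng.unif() - 0.5) / dim;

  double total_updates = (double)total_tokens * epochs;
  double done = 0.0;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      IntegerVector w = walks[i];
      int len = w.size();
      for (int c = 0; c < len; ++c) {
        double alpha = alpha0 * std::max(1e-4, 1.0 - done / (total_updates + 1));
        done += 1.0;
        int center = w[c] - 1;
        double* cen = &syn0[(size_t)center * dim];
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          int j = c + off;
          if (j < 0 || j >= len) continue;
          int ctx = w[j] - 1;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_cum(noise_cum, rng);
              if (target == ctx) continue;
              label = 0.0;
            }
            double* out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += cen[d] * out[d];
            double g = (label - sigmoidd(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * out[d];
              out[d] += g * cen[d];
            }
          }
          for (int d = 0; d < dim; ++d) cen[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix res(n_vocab, dim);
  for (int i = 0; i < n_vocab; ++i)
    for (int d = 0; d < dim; ++d) res(i, d) = syn0[(size_t)i * dim + d];
  return res;
}

// [[Rcpp::export]]
NumericMatrix cpp_train_line(IntegerVector eu, IntegerVector ev,
                             NumericVector ew, int n_nodes, int dim,
                             int order, double n_samples, int negative,
                             double rho0, int seed) {
  Rng rng((uint32_t)seed);
  int n_edges = eu.size();
  std::vector<double> edge_cum(n_edges);
  std::vector<double> deg(n_nodes, 0.0);
  double acc = 0.0;
  for (int i = 0; i < n_edges; ++i) {
    acc += ew[i];
    edge_cum[i] = acc;
    deg[eu[i]] += ew[i];
    deg[ev[i]] += ew[i];
  }
  std::vector<double> noise_cum(n_nodes);
  acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += std::pow(deg[i], 0.75);
    noise_cum[i] = acc;
  }
  std::vector<double> vert((size_t)n_nodes * dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      vert[(size_t)i * dim + d] = (rng.unif() - 0.5) / dim;
  // order-2 trains separate context vectors; order-1 ties them to vert
  std::vector<double> ctxv;
  if (order == 2) ctxv.assign((size_t)n_nodes * dim, 0.0);

  std::vector<double> grad(dim);
  long long total = (long long)n_samples;
  // sampled-objective history in 10 equal bins over training
  int n_bins = 10;
  std::vector<double> bin_loss(n_bins, 0.0);
  std::vector<long long> bin_cnt(n_bins, 0);
  for (long long t = 0; t < total; ++t) {
    double rho = rho0 * std::max(1e-4, 1.0 - (double)t / (total + 1));
    int bin = std::min<long long>(n_bins - 1, t * n_bins / std::max(1LL, total));
    int e = sample_cum(edge_cum, rng);
    int u = eu[e], v = ev[e];
    if (rng.unif() < 0.5) std::swap(u, v);  // undirected: both directions
    double* uv = &vert[(size_t)u * dim];
    std::fill(grad.begin(), grad.end(), 0.0);
    double sloss = 0.0;
    for (int s = 0; s < negative + 1; ++s) {
      int target;
      double label;
      if (s == 0) { target = v; label = 1.0; }
      else {
        target = sample_cum(noise_cum, rng);
        if (target == v || target == u) continue;
        label = 0.0;
      }
      double dot = 0.0;
      double* out = (order == 2) ? &ctxv[(size_t)target * dim]
                                 : &vert[(size_t)target * dim];
      for (int d = 0; d < dim; ++d) dot += uv[d] * out[d];
      double p = sigmoidd(label > 0.5 ? dot : -dot);
      sloss -= std::log(std::max(p, 1e-12));
      double g = (label - sigmoidd(dot)) * rho;
      for (int d = 0; d < dim; ++d) {
        grad[d] += g * out[d];
        out[d] += g * uv[d];
      }
    }
    for (int d = 0; d < dim; ++d) uv[d] += grad[d];
    bin_loss[bin] += sloss;
    bin_cnt[bin] += 1;
  }
  NumericMatrix res(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) res(i, d) = vert[(size_t)i * dim + d];
  NumericVector hist(n_bins);
  for (int b = 0; b < n_bins; ++b)
    hist[b] = bin_cnt[b] > 0 ? bin_loss[b] / bin_cnt[b] : NA_REAL;
  res.attr("lossHistory") = hist;
  return res;
}
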