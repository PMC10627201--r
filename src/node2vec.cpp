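#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adjacency is CSR: off[i]..off[i+1]-1 indexes into nbr (0-based node ids,
// sorted ascending per node) and wt (edge weights).

static inline bool is_neighbor(const IntegerVector &nbr, const IntegerVector &off,
                               int u, int x) {
  int lo = off[u], hi = off[u + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (nbr[mid] == x) return true;
    if (nbr[mid] < x) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

static int sample_cum(const std::vector<double> &cum, double total) {
  double r = unif_rand() * total;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < r) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Biased second-order random walks (return parameter p, in-out parameter q).
// Returns an (n_nodes * walks_per_node) x walk_len matrix of 0-based node
// ids; positions past a stuck walk are filled with -1.
// [[Rcpp::export]]
IntegerMatrix cpp_node2vec_walks(IntegerVector nbr, NumericVector wt,
                                 IntegerVector off, int n_nodes,
                                 double p, double q, int walk_len,
                                 int walks_per_node) {
  IntegerMatrix walks(n_nodes * walks_per_node, walk_len);
  std::vector<double> cum;
  int row = 0;
  for (int w = 0; w < walks_per_node; ++w) {
    for (int u = 0; u < n_nodes; ++u, ++row) {
      int prev = -1, cur = u;
      walks(row, 0) = u;
      for (int step = 1; step < walk_len; ++step) {
        int a = off[cur], b = off[cur + 1];
        int deg = b - a;
        if (deg == 0) { // isolated: walk ends
          for (int s = step; s < walk_len; ++s) walks(row, s) = -1;
          break;
        }
        cum.resize(deg);
        double tot = 0.0;
        for (int j = 0; j < deg; ++j) {
          int x = nbr[a + j];
          double bias = 1.0;
          if (prev >= 0) {
            if (x == prev) bias = 1.0 / p;
            else if (!is_neighbor(nbr, off, prev, x)) bias = 1.0 / q;
          }
          tot += wt[a + j] * bias;
          cum[j] = tot;
        }
        int j = sample_cum(cum, tot);
        prev = cur;
        cur = nbr[a + j];
        walks(row, step) = cur;
      }
    }
  }
  return walks;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus (word2vec SGD,
// dynamic window, unigram^0.75 negative distribution, linear lr decay).
// Returns the n_nodes x dim input-embedding matrix.
// [[Rcpp::export]]
NumericMatrix cpp_skipgram(IntegerMatrix walks, int n_nodes, int dim,
                           int window, int epochs, int negative,
                           double alpha0) {
  const int n_walks = walks.nrow(), wlen = walks.ncol();
  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> freq(n_nodes, 0.0);
  for (int r = 0; r < n_walks; ++r)
    for (int c = 0; c < wlen; ++c)
      if (walks(r, c) >= 0) freq[walks(r, c)] += 1.0;
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(freq[i], 0.75);
    cum[i] = tot;
  }
  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif_rand() - 0.5) / dim;
  const double total_tokens = (double)epochs * n_walks * wlen;
  double processed = 0.0;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < n_walks; ++r) {
      for (int c = 0; c < wlen; ++c, processed += 1.0) {
        int center = walks(r, c);
        if (center < 0) continue;
        double alpha = alpha0 * (1.0 - processed / total_tokens);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int b = (int)(unif_rand() * window); // dynamic window shrink
        for (int d = b - window; d <= window - b; ++d) {
          if (d == 0) continue;
          int cc = c + d;
          if (cc < 0 || cc >= wlen) continue;
          int ctx = walks(r, cc);
          if (ctx < 0) continue;
          double *v = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_cum(cum, tot);
              if (target == ctx) continue;
              label = 0.0;
            }
            double *u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * u[k];
            double g = (label - sigmoid(dot)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u[k];
              u[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }
  NumericMatrix E(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k)
      E(i, k) = syn0[(size_t)i * dim + k];
  return E;
}
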