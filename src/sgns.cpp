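// Skip-gram word embeddings with negative sampling, single-threaded and
// deterministic given the seed.  Token ids are 1-based on entry (0 = padding
// is never passed in).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

// xorshift64* PRNG: deterministic across platforms, cheap
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export]]
arma::mat cpp_sgns_train(Rcpp::List docs, int vocab_size, int dim,
                         int window, int epochs, int negative,
                         double alpha, int seed) {
  const int V = vocab_size, D = dim;
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram counts -> negative-sampling table with 3/4 smoothing
  arma::vec counts(V, arma::fill::zeros);
  long long total_tokens = 0;
  for (int i = 0; i < docs.size(); ++i) {
    Rcpp::IntegerVector d = docs[i];
    for (int j = 0; j < d.size(); ++j) {
      int w = d[j] - 1;
      if (w >= 0 && w < V) { counts[w] += 1.0; ++total_tokens; }
    }
  }
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    arma::vec p = arma::pow(counts + 1e-12, 0.75);
    p /= arma::accu(p);
    arma::vec cp = arma::cumsum(p);
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      double u = (i + 0.5) / table_size;
      while (w < V - 1 && cp[w] < u) ++w;
      table[i] = w;
    }
  }

  arma::mat syn0(D, V), syn1(D, V, arma::fill::zeros);
  for (arma::uword i = 0; i < syn0.n_elem; ++i)
    syn0[i] = (rng.unif() - 0.5) / D;

  const long long total_work =
      static_cast<long long>(epochs) * std::max(1LL, total_tokens);
  long long done = 0;
  arma::vec neu1e(D);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int di = 0; di < docs.size(); ++di) {
      Rcpp::IntegerVector d = docs[di];
      const int n = d.size();
      for (int i = 0; i < n; ++i) {
        int w = d[i] - 1;
        ++done;
        if (w < 0 || w >= V) continue;
        double lr = alpha * (1.0 - static_cast<double>(done) / (total_work + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        int b = 1 + rng.below(window);
        for (int j = i - b; j <= i + b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          int c = d[j] - 1;
          if (c < 0 || c >= V) continue;
          neu1e.zeros();
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = c; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == c) continue;
              label = 0.0;
            }
            double f = arma::dot(syn0.col(w), syn1.col(target));
            double g = (label - sigmoid(f)) * lr;
            neu1e += g * syn1.col(target);
            syn1.col(target) += g * syn0.col(w);
          }
          syn0.col(w) += neu1e;
        }
      }
    }
  }
  return syn0.t();  // V x D, one row per token
}
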