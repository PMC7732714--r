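#ifndef REDSUP_NN_COMMON_H
#define REDSUP_NN_COMMON_H

#include <RcppArmadillo.h>

namespace redsup {

// xorshift64* PRNG, deterministic across platforms
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  // uniform in (-r, r)
  void fill_uniform(arma::mat& m, double r) {
    for (arma::uword i = 0; i < m.n_elem; ++i) m[i] = (unif() * 2.0 - 1.0) * r;
  }
  void fill_uniform(arma::vec& v, double r) {
    for (arma::uword i = 0; i < v.n_elem; ++i) v[i] = (unif() * 2.0 - 1.0) * r;
  }
  // Fisher-Yates permutation of 0..n-1
  std::vector<int> permutation(int n) {
    std::vector<int> p(n);
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(p[i], p[below(i + 1)]);
    return p;
  }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Adam optimizer state for one parameter matrix
struct Adam {
  arma::mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const arma::mat& p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
  void step(arma::mat& p, const arma::mat& g, double lr) {
    ++t;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

inline double bce_loss(const arma::vec& p, const arma::vec& y) {
  arma::vec q = arma::clamp(p, 1e-10, 1 - 1e-10);
  return -arma::mean(y % arma::log(q) + (1 - y) % arma::log(1 - q));
}

} // namespace redsup

#endif
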