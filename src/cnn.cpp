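// Convolutional text classifier: learned word-embedding layer (optional
// fixed character-embedding channel concatenated per position), parallel
// 1-d convolutions with ReLU and max-over-time pooling, an optional
// document-level side vector concatenated before one dense hidden layer,
// and a sigmoid output trained with cross-entropy (Adam).
#include "nn_common.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace redsup;

namespace {

struct CnnShape {
  int V, d, dim_in, n_filters, hidden, S;
  std::vector<int> fs;
  bool use_char;
};

// embedded doc (dim_in x L) for one row of X, before dropout
void embed_doc(const arma::imat& X, int i, const arma::mat& E,
               const arma::mat& C, bool use_char, arma::mat& out) {
  const int L = X.n_cols, d = E.n_cols;
  for (int t = 0; t < L; ++t) {
    int w = X(i, t);
    out.submat(0, t, d - 1, t) = E.row(w).t();
    if (use_char) out.submat(d, t, 2 * d - 1, t) = C.row(w).t();
  }
}

void apply_dropout(arma::mat& x, double rate, Rng& rng) {
  if (rate <= 0) return;
  const double scale = 1.0 / (1.0 - rate);
  for (arma::uword i = 0; i < x.n_elem; ++i)
    x[i] = (rng.unif() < rate) ? 0.0 : x[i] * scale;
}

// stacked windows for filter size h: (h*dim_in) x (L-h+1); columns of the
// embedded doc are contiguous so each window is one memcpy
arma::mat stack_windows(const arma::mat& xe, int h) {
  const int dim_in = xe.n_rows, L = xe.n_cols, P = L - h + 1;
  arma::mat s(h * dim_in, P);
  for (int t = 0; t < P; ++t)
    std::memcpy(s.colptr(t), xe.colptr(t), sizeof(double) * h * dim_in);
  return s;
}

// forward conv+pool for one doc; fills pooled (n_filters per size, stacked)
// and argmax positions
void conv_forward(const arma::mat& xe, const CnnShape& sh,
                  const std::vector<arma::mat>& W,
                  const std::vector<arma::vec>& b,
                  arma::vec& pooled, arma::ivec& amax) {
  int off = 0;
  for (size_t k = 0; k < sh.fs.size(); ++k) {
    arma::mat s = stack_windows(xe, sh.fs[k]);
    arma::mat z = W[k].t() * s;           // F x P
    z.each_col() += b[k];
    z.transform([](double v) { return v > 0 ? v : 0.0; });
    for (int f = 0; f < sh.n_filters; ++f) {
      arma::uword t;
      pooled[off + f] = z.row(f).max(t);
      amax[off + f] = static_cast<int>(t);
    }
    off += sh.n_filters;
  }
}

uint64_t mix_seed(int seed, long a, long b) {
  uint64_t x = static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL;
  x ^= static_cast<uint64_t>(a + 1) * 0xbf58476d1ce4e5b9ULL;
  x ^= static_cast<uint64_t>(b + 1) * 0x94d049bb133111ebULL;
  return x ? x : 1ULL;
}

arma::vec forward_all(const arma::imat& X, const arma::mat& side,
                      const CnnShape& sh, const arma::mat& E,
                      const arma::mat& C, const std::vector<arma::mat>& W,
                      const std::vector<arma::vec>& b, const arma::mat& W1,
                      const arma::vec& b1, const arma::vec& w2, double b2) {
  const int n = X.n_rows;
  const int FF = sh.n_filters * static_cast<int>(sh.fs.size());
  arma::vec out(n);
  arma::mat xe(sh.dim_in, X.n_cols);
  arma::vec pooled(FF);
  arma::ivec amax(FF);
  for (int i = 0; i < n; ++i) {
    embed_doc(X, i, E, C, sh.use_char, xe);
    conv_forward(xe, sh, W, b, pooled, amax);
    arma::vec u(FF + sh.S);
    u.head(FF) = pooled;
    if (sh.S > 0) u.tail(sh.S) = side.row(i).t();
    arma::vec a = W1.t() * u + b1;
    a.transform([](double v) { return v > 0 ? v : 0.0; });
    out[i] = sigmoid(arma::dot(w2, a) + b2);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::imat& X, const arma::vec& y,
                         const arma::mat& side, const arma::mat& emb_init,
                         const arma::mat& char_emb, int vocab_size,
                         int emb_dim, Rcpp::IntegerVector filter_sizes,
                         int n_filters, int hidden, double dropout,
                         int batch_size, int epochs, double lr, int seed,
                         const arma::imat& X_val, const arma::vec& y_val,
                         const arma::mat& side_val) {
  CnnShape sh;
  sh.V = vocab_size; sh.d = emb_dim;
  sh.use_char = char_emb.n_rows > 0;
  sh.dim_in = sh.use_char ? 2 * sh.d : sh.d;
  sh.n_filters = n_filters; sh.hidden = hidden;
  sh.S = side.n_cols;
  for (int i = 0; i < filter_sizes.size(); ++i)
    sh.fs.push_back(filter_sizes[i]);
  const int n = X.n_rows, L = X.n_cols;
  const int FF = sh.n_filters * static_cast<int>(sh.fs.size());
  for (int k : sh.fs)
    if (k > L) Rcpp::stop("filter size %d exceeds sequence length %d", k, L);

  Rng rng(mix_seed(seed, 0, 0));
  arma::mat E;
  if (emb_init.n_rows > 0) E = emb_init;
  else { E.set_size(sh.V, sh.d); rng.fill_uniform(E, 0.05); }

  std::vector<arma::mat> W(sh.fs.size());
  std::vector<arma::vec> b(sh.fs.size());
  std::vector<Adam> aW(sh.fs.size()), ab(sh.fs.size());
  for (size_t k = 0; k < sh.fs.size(); ++k) {
    W[k].set_size(sh.fs[k] * sh.dim_in, sh.n_filters);
    rng.fill_uniform(W[k], std::sqrt(6.0 / (sh.fs[k] * sh.dim_in + sh.n_filters)));
    b[k].zeros(sh.n_filters);
    aW[k].init(W[k]); ab[k].init(b[k]);
  }
  arma::mat W1(FF + sh.S, sh.hidden);
  rng.fill_uniform(W1, std::sqrt(6.0 / (FF + sh.S + sh.hidden)));
  arma::vec b1(sh.hidden, arma::fill::zeros);
  arma::vec w2(sh.hidden); rng.fill_uniform(w2, std::sqrt(6.0 / sh.hidden));
  double b2 = 0.0;
  Adam aE, aW1, ab1, aw2, ab2;
  aE.init(E); aW1.init(W1); ab1.init(b1); aw2.init(w2);
  arma::mat b2m(1, 1); b2m(0, 0) = b2; ab2.init(b2m);

  std::vector<double> train_loss, val_loss;
  arma::mat xe(sh.dim_in, L);
  const int FFS = FF + sh.S;

  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> perm = rng.permutation(n);
    double ep_loss = 0.0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      // pass 1: conv forward per doc, record pooled + argmax
      arma::mat U(FFS, B);
      arma::imat AM(FF, B);
      for (int bi = 0; bi < B; ++bi) {
        int i = perm[start + bi];
        embed_doc(X, i, E, char_emb, sh.use_char, xe);
        Rng drng(mix_seed(seed, ep * 100003L + start, bi));
        apply_dropout(xe, dropout, drng);
        arma::vec pooled(FF); arma::ivec amax(FF);
        conv_forward(xe, sh, W, b, pooled, amax);
        U.col(bi).head(FF) = pooled;
        if (sh.S > 0) U.col(bi).tail(sh.S) = side.row(i).t();
        AM.col(bi) = amax;
      }
      // dense forward (batched)
      arma::mat A = W1.t() * U; A.each_col() += b1;
      arma::mat Arelu = A;
      Arelu.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::vec logits = Arelu.t() * w2 + b2;
      arma::vec p(B), yb(B);
      for (int bi = 0; bi < B; ++bi) {
        p[bi] = sigmoid(logits[bi]);
        yb[bi] = y[perm[start + bi]];
      }
      double loss = bce_loss(p, yb);
      if (!std::isfinite(loss))
        Rcpp::stop("NaN loss in CNN training at epoch %d, batch %d",
                   ep + 1, start / batch_size + 1);
      ep_loss += loss; ++n_batches;

      // dense backward
      arma::vec dlogit = (p - yb) / B;
      arma::vec gw2 = Arelu * dlogit;
      double gb2 = arma::accu(dlogit);
      arma::mat dA = w2 * dlogit.t();               // H x B
      dA.elem(arma::find(A <= 0)).zeros();
      arma::mat gW1 = U * dA.t();
      arma::vec gb1 = arma::sum(dA, 1);
      arma::mat dU = W1 * dA;                       // FFS x B

      // pass 2: conv backward per doc
      std::vector<arma::mat> gW(sh.fs.size());
      std::vector<arma::vec> gb(sh.fs.size());
      for (size_t k = 0; k < sh.fs.size(); ++k) {
        gW[k].zeros(W[k].n_rows, W[k].n_cols);
        gb[k].zeros(sh.n_filters);
      }
      arma::mat gE(sh.V, sh.d, arma::fill::zeros);
      const double scale = dropout > 0 ? 1.0 / (1.0 - dropout) : 1.0;
      for (int bi = 0; bi < B; ++bi) {
        int i = perm[start + bi];
        embed_doc(X, i, E, char_emb, sh.use_char, xe);
        Rng drng(mix_seed(seed, ep * 100003L + start, bi));
        arma::mat mask(sh.dim_in, L, arma::fill::ones);
        if (dropout > 0)
          for (arma::uword q = 0; q < mask.n_elem; ++q)
            if (drng.unif() < dropout) mask[q] = 0.0;
        arma::mat xdrop = xe % mask * scale;
        arma::mat dX(sh.dim_in, L, arma::fill::zeros);
        int off = 0;
        for (size_t k = 0; k < sh.fs.size(); ++k) {
          const int h = sh.fs[k];
          for (int f = 0; f < sh.n_filters; ++f) {
            double g = dU(off + f, bi);
            double pooled_v = U(off + f, bi);
            if (g == 0.0 || pooled_v <= 0.0) continue;  // relu off or no grad
            int t = AM(off + f, bi);
            arma::vec win(h * sh.dim_in);
            std::memcpy(win.memptr(), xdrop.colptr(t),
                        sizeof(double) * h * sh.dim_in);
            gW[k].col(f) += g * win;
            gb[k][f] += g;
            arma::vec dwin = g * W[k].col(f);
            for (int c = 0; c < h; ++c)
              dX.col(t + c) += dwin.subvec(c * sh.dim_in,
                                           (c + 1) * sh.dim_in - 1);
          }
          off += sh.n_filters;
        }
        // through dropout into the learned word-embedding rows
        dX = dX % mask * scale;
        for (int t = 0; t < L; ++t)
          gE.row(X(i, t)) += dX.col(t).head(sh.d).t();
      }
      for (size_t k = 0; k < sh.fs.size(); ++k) {
        aW[k].step(W[k], gW[k], lr);
        arma::mat gbm(gb[k]); arma::mat bm(b[k]);
        ab[k].step(bm, gbm, lr); b[k] = bm.col(0);
      }
      aE.step(E, gE, lr);
      aW1.step(W1, gW1, lr);
      { arma::mat bm(b1), gm(gb1); ab1.step(bm, gm, lr); b1 = bm.col(0); }
      { arma::mat wm(w2), gm(gw2); aw2.step(wm, gm, lr); w2 = wm.col(0); }
      { arma::mat gm(1, 1); gm(0, 0) = gb2; ab2.step(b2m, gm, lr);
        b2 = b2m(0, 0); }
    }
    train_loss.push_back(ep_loss / std::max(1, n_batches));
    if (X_val.n_rows > 0) {
      arma::vec pv = forward_all(X_val, side_val, sh, E,
                                 char_emb, W, b, W1, b1, w2, b2);
      val_loss.push_back(bce_loss(pv, y_val));
    }
  }

  Rcpp::List Wl(sh.fs.size()), bl(sh.fs.size());
  for (size_t k = 0; k < sh.fs.size(); ++k) { Wl[k] = W[k]; bl[k] = b[k]; }
  return Rcpp::List::create(
      Rcpp::Named("embedding") = E, Rcpp::Named("conv_w") = Wl,
      Rcpp::Named("conv_b") = bl, Rcpp::Named("dense_w") = W1,
      Rcpp::Named("dense_b") = b1, Rcpp::Named("out_w") = w2,
      Rcpp::Named("out_b") = b2,
      Rcpp::Named("filter_sizes") = filter_sizes,
      Rcpp::Named("n_filters") = n_filters,
      Rcpp::Named("use_char") = sh.use_char,
      Rcpp::Named("train_loss") = train_loss,
      Rcpp::Named("val_loss") = val_loss);
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(const Rcpp::List& model, const arma::imat& X,
                          const arma::mat& side, const arma::mat& char_emb) {
  arma::mat E = model["embedding"];
  Rcpp::List Wl = model["conv_w"], bl = model["conv_b"];
  CnnShape sh;
  sh.V = E.n_rows; sh.d = E.n_cols;
  sh.use_char = Rcpp::as<bool>(model["use_char"]);
  sh.dim_in = sh.use_char ? 2 * sh.d : sh.d;
  sh.n_filters = Rcpp::as<int>(model["n_filters"]);
  Rcpp::IntegerVector fs = model["filter_sizes"];
  for (int i = 0; i < fs.size(); ++i) sh.fs.push_back(fs[i]);
  sh.S = side.n_cols;
  std::vector<arma::mat> W(sh.fs.size());
  std::vector<arma::vec> b(sh.fs.size());
  for (size_t k = 0; k < sh.fs.size(); ++k) {
    W[k] = Rcpp::as<arma::mat>(Wl[k]);
    b[k] = Rcpp::as<arma::vec>(bl[k]);
  }
  arma::mat W1 = model["dense_w"];
  arma::vec b1 = model["dense_b"], w2 = model["out_w"];
  double b2 = model["out_b"];
  return forward_all(X, side, sh, E, char_emb, W, b, W1, b1, w2, b2);
}
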