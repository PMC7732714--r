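// LSTM text classifiers over padded index sequences: a unidirectional LSTM
// reading out its final hidden state, and a bidirectional LSTM with
// additive attention pooling over all positions.  The word-embedding layer
// is learned jointly.  Training is mini-batch Adam on cross-entropy with
// full backpropagation through time; padded positions carry state through
// unchanged and contribute no gradient.
#include "nn_common.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace redsup;

namespace {

struct DirParams {
  arma::mat W;   // d x 4H   gate order: input, forget, candidate, output
  arma::mat U;   // H x 4H
  arma::rowvec b;  // 4H
};

struct DirGrads {
  arma::mat W, U;
  arma::rowvec b;
  void zeros(const DirParams& p) {
    W.zeros(p.W.n_rows, p.W.n_cols);
    U.zeros(p.U.n_rows, p.U.n_cols);
    b.zeros(p.b.n_elem);
  }
};

struct DirCache {
  std::vector<arma::mat> gi, gf, gg, go, c, tc, h;  // each B x H per step
};

uint64_t mix_seed(int seed, long a) {
  uint64_t x = static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL;
  x ^= static_cast<uint64_t>(a + 1) * 0xbf58476d1ce4e5b9ULL;
  return x ? x : 1ULL;
}

arma::mat gather_embed(const arma::mat& E, const arma::imat& Xb,
                       const std::vector<int>& rows, int t) {
  arma::mat x(rows.size(), E.n_cols);
  for (size_t i = 0; i < rows.size(); ++i)
    x.row(i) = E.row(Xb(rows[i], t));
  return x;
}

// forward over T steps for one direction; Xb indexed by rows/col_of(t)
void dir_forward(const arma::mat& E, const arma::imat& Xb,
                 const std::vector<int>& rows,
                 const std::vector<std::vector<int>>& cols,
                 const arma::vec& len, int T, const DirParams& P,
                 DirCache& ca) {
  const int B = rows.size(), H = P.U.n_rows;
  ca.gi.assign(T, arma::mat()); ca.gf.assign(T, arma::mat());
  ca.gg.assign(T, arma::mat()); ca.go.assign(T, arma::mat());
  ca.c.assign(T, arma::mat()); ca.tc.assign(T, arma::mat());
  ca.h.assign(T, arma::mat());
  arma::mat h_prev(B, H, arma::fill::zeros), c_prev(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat x(B, E.n_cols);
    for (int i = 0; i < B; ++i)
      x.row(i) = E.row(Xb(rows[i], cols[i][t]));
    arma::mat pre = x * P.W + h_prev * P.U;
    pre.each_row() += P.b;
    arma::mat gi = pre.cols(0, H - 1), gf = pre.cols(H, 2 * H - 1),
              gg = pre.cols(2 * H, 3 * H - 1), go = pre.cols(3 * H, 4 * H - 1);
    gi.transform([](double v) { return sigmoid(v); });
    gf.transform([](double v) { return sigmoid(v); });
    gg = arma::tanh(gg);
    go.transform([](double v) { return sigmoid(v); });
    arma::mat c_new = gf % c_prev + gi % gg;
    arma::mat tc = arma::tanh(c_new);
    arma::mat h_new = go % tc;
    arma::vec m(B);
    for (int i = 0; i < B; ++i) m[i] = (t < len[i]) ? 1.0 : 0.0;
    arma::mat c_t = c_new, h_t = h_new;
    c_t.each_col() %= m; h_t.each_col() %= m;
    arma::mat keep = c_prev; keep.each_col() %= (1 - m);
    c_t += keep;
    keep = h_prev; keep.each_col() %= (1 - m);
    h_t += keep;
    ca.gi[t] = gi; ca.gf[t] = gf; ca.gg[t] = gg; ca.go[t] = go;
    ca.c[t] = c_t; ca.tc[t] = tc; ca.h[t] = h_t;
    h_prev = ca.h[t]; c_prev = ca.c[t];
  }
}

// backward through time; dH[t] holds dLoss/dh_t contributions from the head
void dir_backward(const arma::mat& E, const arma::imat& Xb,
                  const std::vector<int>& rows,
                  const std::vector<std::vector<int>>& cols,
                  const arma::vec& len, int T, const DirParams& P,
                  const DirCache& ca, const std::vector<arma::mat>& dH,
                  DirGrads& g, arma::mat& gE) {
  const int B = rows.size(), H = P.U.n_rows;
  arma::mat dh(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH[t];
    arma::vec m(B);
    for (int i = 0; i < B; ++i) m[i] = (t < len[i]) ? 1.0 : 0.0;
    arma::mat dh_new = dh, dc_new = dc;
    dh_new.each_col() %= m; dc_new.each_col() %= m;
    arma::mat dh_carry = dh, dc_carry = dc;
    dh_carry.each_col() %= (1 - m); dc_carry.each_col() %= (1 - m);

    const arma::mat& gi = ca.gi[t]; const arma::mat& gf = ca.gf[t];
    const arma::mat& gg = ca.gg[t]; const arma::mat& go = ca.go[t];
    const arma::mat& tc = ca.tc[t];
    arma::mat c_prev = (t == 0) ? arma::mat(B, H, arma::fill::zeros)
                                : ca.c[t - 1];
    arma::mat h_prev = (t == 0) ? arma::mat(B, H, arma::fill::zeros)
                                : ca.h[t - 1];

    arma::mat dgo = dh_new % tc;
    dc_new += (dh_new % go) % (1 - tc % tc);
    arma::mat dgi = dc_new % gg;
    arma::mat dgg = dc_new % gi;
    arma::mat dgf = dc_new % c_prev;
    arma::mat dc_prev = dc_new % gf;

    arma::mat da(B, 4 * H);
    da.cols(0, H - 1) = dgi % gi % (1 - gi);
    da.cols(H, 2 * H - 1) = dgf % gf % (1 - gf);
    da.cols(2 * H, 3 * H - 1) = dgg % (1 - gg % gg);
    da.cols(3 * H, 4 * H - 1) = dgo % go % (1 - go);

    arma::mat x(B, E.n_cols);
    for (int i = 0; i < B; ++i)
      x.row(i) = E.row(Xb(rows[i], cols[i][t]));
    g.W += x.t() * da;
    g.U += h_prev.t() * da;
    g.b += arma::sum(da, 0);
    arma::mat dx = da * P.W.t();
    for (int i = 0; i < B; ++i)
      if (t < len[i]) gE.row(Xb(rows[i], cols[i][t])) += dx.row(i);
    dh = dh_carry + da * P.U.t();
    dc = dc_carry + dc_prev;
  }
}

struct Head {
  bool attention, bidirectional;
  arma::mat Wa;      // D2 x Ha
  arma::rowvec ba;   // Ha
  arma::vec v;       // Ha
  arma::vec w_out;   // D2
  double b_out;
};

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(const arma::imat& X, const arma::vec& lengths,
                          const arma::vec& y, const arma::mat& emb_init,
                          int vocab_size, int emb_dim, int hidden,
                          bool bidirectional, bool attention, int batch_size,
                          int epochs, double lr, int seed,
                          const arma::imat& X_val, const arma::vec& len_val,
                          const arma::vec& y_val) {
  const int n = X.n_rows, L = X.n_cols, H = hidden, d = emb_dim;
  const int D2 = bidirectional ? 2 * H : H;
  Rng rng(mix_seed(seed, 0));

  arma::mat E;
  if (emb_init.n_rows > 0) E = emb_init;
  else { E.set_size(vocab_size, d); rng.fill_uniform(E, 0.05); }

  auto init_dir = [&](DirParams& P) {
    P.W.set_size(d, 4 * H); rng.fill_uniform(P.W, std::sqrt(6.0 / (d + H)));
    P.U.set_size(H, 4 * H); rng.fill_uniform(P.U, std::sqrt(6.0 / (2 * H)));
    P.b.zeros(4 * H);
    P.b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias
  };
  DirParams Pf, Pb;
  init_dir(Pf);
  if (bidirectional) init_dir(Pb);

  Head hd; hd.attention = attention; hd.bidirectional = bidirectional;
  if (attention) {
    hd.Wa.set_size(D2, H); rng.fill_uniform(hd.Wa, std::sqrt(6.0 / (D2 + H)));
    hd.ba.zeros(H);
    hd.v.set_size(H); rng.fill_uniform(hd.v, std::sqrt(6.0 / H));
  }
  hd.w_out.set_size(D2); rng.fill_uniform(hd.w_out, std::sqrt(6.0 / D2));
  hd.b_out = 0.0;

  Adam aE, aWf, aUf, abf, aWb, aUb, abb, aWa, aba, av, awo, abo;
  aE.init(E);
  aWf.init(Pf.W); aUf.init(Pf.U); abf.init(arma::mat(Pf.b.t()));
  if (bidirectional) {
    aWb.init(Pb.W); aUb.init(Pb.U); abb.init(arma::mat(Pb.b.t()));
  }
  if (attention) {
    aWa.init(hd.Wa); aba.init(arma::mat(hd.ba.t())); av.init(arma::mat(hd.v));
  }
  awo.init(arma::mat(hd.w_out));
  arma::mat bom(1, 1); bom(0, 0) = 0.0; abo.init(bom);

  std::vector<double> train_loss;
  (void)X_val; (void)len_val; (void)y_val;

  // forward + (optionally) backward over one batch; returns probabilities
  auto run_batch = [&](const std::vector<int>& rows,
                       bool train_mode) -> arma::vec {
    const int B = rows.size();
    int T = 1;
    arma::vec len(B);
    for (int i = 0; i < B; ++i) {
      len[i] = std::max(1.0, std::min((double)L, lengths[rows[i]]));
      T = std::max(T, (int)len[i]);
    }
    // forward direction reads t; backward direction reads len-1-t
    std::vector<std::vector<int>> cols_f(B, std::vector<int>(T)),
        cols_b(B, std::vector<int>(T));
    for (int i = 0; i < B; ++i)
      for (int t = 0; t < T; ++t) {
        cols_f[i][t] = t;
        cols_b[i][t] = (t < len[i]) ? (int)len[i] - 1 - t : t;
      }
    DirCache cf, cb;
    dir_forward(E, X, rows, cols_f, len, T, Pf, cf);
    if (bidirectional) dir_forward(E, X, rows, cols_b, len, T, Pb, cb);

    // aligned concatenated states per original position (attention head)
    std::vector<arma::mat> hcat, uatt;
    arma::mat alpha, ctx;
    arma::vec logits(B);
    if (attention) {
      hcat.assign(T, arma::mat(B, D2));
      uatt.assign(T, arma::mat());
      arma::mat e(B, T, arma::fill::value(-1e30));
      for (int t = 0; t < T; ++t) {
        hcat[t].cols(0, H - 1) = cf.h[t];
        if (bidirectional) {
          for (int i = 0; i < B; ++i) {
            int tb = (int)len[i] - 1 - t;  // backward step holding orig pos t
            if (t < len[i]) hcat[t].row(i).cols(H, D2 - 1) = cb.h[tb].row(i);
            else hcat[t].row(i).cols(H, D2 - 1).zeros();
          }
        }
        arma::mat u = arma::tanh(hcat[t] * hd.Wa +
                                 arma::repmat(hd.ba, B, 1));
        uatt[t] = u;
        arma::vec et = u * hd.v;
        for (int i = 0; i < B; ++i) if (t < len[i]) e(i, t) = et[i];
      }
      // masked softmax over positions
      alpha.set_size(B, T);
      for (int i = 0; i < B; ++i) {
        arma::rowvec r = e.row(i);
        double mx = r.max();
        r = arma::exp(r - mx);
        alpha.row(i) = r / arma::accu(r);
      }
      ctx.zeros(B, D2);
      for (int t = 0; t < T; ++t)
        ctx += hcat[t].each_col() % alpha.col(t);
      logits = ctx * hd.w_out + hd.b_out;
    } else {
      arma::mat hfin(B, D2);
      hfin.cols(0, H - 1) = cf.h[T - 1];
      if (bidirectional) hfin.cols(H, D2 - 1) = cb.h[T - 1];
      logits = hfin * hd.w_out + hd.b_out;
      ctx = hfin;  // reuse for backward
    }
    arma::vec p(B);
    for (int i = 0; i < B; ++i) p[i] = sigmoid(logits[i]);
    if (!train_mode) return p;

    // ---- backward ----
    arma::vec yb(B);
    for (int i = 0; i < B; ++i) yb[i] = y[rows[i]];
    arma::vec dlogit = (p - yb) / B;
    arma::vec gwo = ctx.t() * dlogit;
    double gbo = arma::accu(dlogit);

    std::vector<arma::mat> dHf(T, arma::mat(B, H, arma::fill::zeros)),
        dHb(T, arma::mat(B, H, arma::fill::zeros));
    arma::mat gWa, gv; arma::rowvec gba;
    if (attention) {
      gWa.zeros(hd.Wa.n_rows, hd.Wa.n_cols);
      gba.zeros(hd.ba.n_elem);
      gv = arma::mat(H, 1, arma::fill::zeros);
      arma::mat dctx = dlogit * hd.w_out.t();   // B x D2
      arma::mat dalpha(B, T, arma::fill::zeros);
      std::vector<arma::mat> dhcat(T, arma::mat(B, D2, arma::fill::zeros));
      for (int t = 0; t < T; ++t) {
        dalpha.col(t) = arma::sum(dctx % hcat[t], 1);
        dhcat[t] = dctx.each_col() % alpha.col(t);
      }
      arma::vec s = arma::sum(dalpha % alpha, 1);
      arma::mat de = alpha % (dalpha.each_col() - s);
      for (int t = 0; t < T; ++t) {
        arma::vec det = de.col(t);
        arma::mat du = det * hd.v.t();          // B x Ha
        arma::mat dau = du % (1 - uatt[t] % uatt[t]);
        gWa += hcat[t].t() * dau;
        gba += arma::sum(dau, 0);
        gv += uatt[t].t() * det;
        dhcat[t] += dau * hd.Wa.t();
      }
      for (int t = 0; t < T; ++t) {
        dHf[t] = dhcat[t].cols(0, H - 1);
        if (bidirectional)
          for (int i = 0; i < B; ++i)
            if (t < len[i])
              dHb[(int)len[i] - 1 - t].row(i) += dhcat[t].row(i).cols(H, D2 - 1);
      }
    } else {
      arma::mat dhfin = dlogit * hd.w_out.t();  // B x D2
      dHf[T - 1] = dhfin.cols(0, H - 1);
      if (bidirectional) dHb[T - 1] = dhfin.cols(H, D2 - 1);
    }

    DirGrads gf_, gb_;
    gf_.zeros(Pf);
    arma::mat gE(E.n_rows, E.n_cols, arma::fill::zeros);
    dir_backward(E, X, rows, cols_f, len, T, Pf, cf, dHf, gf_, gE);
    if (bidirectional) {
      gb_.zeros(Pb);
      dir_backward(E, X, rows, cols_b, len, T, Pb, cb, dHb, gb_, gE);
    }

    aE.step(E, gE, lr);
    aWf.step(Pf.W, gf_.W, lr); aUf.step(Pf.U, gf_.U, lr);
    { arma::mat bm(Pf.b.t()), gm(gf_.b.t()); abf.step(bm, gm, lr);
      Pf.b = bm.col(0).t(); }
    if (bidirectional) {
      aWb.step(Pb.W, gb_.W, lr); aUb.step(Pb.U, gb_.U, lr);
      arma::mat bm(Pb.b.t()), gm(gb_.b.t()); abb.step(bm, gm, lr);
      Pb.b = bm.col(0).t();
    }
    if (attention) {
      aWa.step(hd.Wa, gWa, lr);
      { arma::mat bm(hd.ba.t()), gm(gba.t()); aba.step(bm, gm, lr);
        hd.ba = bm.col(0).t(); }
      { arma::mat vm(hd.v); av.step(vm, gv, lr); hd.v = vm.col(0); }
    }
    { arma::mat wm(hd.w_out), gm(gwo); awo.step(wm, gm, lr);
      hd.w_out = wm.col(0); }
    { arma::mat gm(1, 1); gm(0, 0) = gbo; abo.step(bom, gm, lr);
      hd.b_out = bom(0, 0); }
    return p;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> perm = rng.permutation(n);
    double ep_loss = 0.0; int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      std::vector<int> rows(perm.begin() + start, perm.begin() + start + B);
      arma::vec p = run_batch(rows, true);
      arma::vec yb(B);
      for (int i = 0; i < B; ++i) yb[i] = y[rows[i]];
      double loss = bce_loss(p, yb);
      if (!std::isfinite(loss))
        Rcpp::stop("NaN loss in LSTM training at epoch %d, batch %d",
                   ep + 1, start / batch_size + 1);
      ep_loss += loss; ++nb;
    }
    train_loss.push_back(ep_loss / std::max(1, nb));
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("embedding") = E,
      Rcpp::Named("Wf") = Pf.W, Rcpp::Named("Uf") = Pf.U,
      Rcpp::Named("bf") = arma::vec(Pf.b.t()),
      Rcpp::Named("bidirectional") = bidirectional,
      Rcpp::Named("attention") = attention,
      Rcpp::Named("hidden") = H,
      Rcpp::Named("out_w") = hd.w_out, Rcpp::Named("out_b") = hd.b_out,
      Rcpp::Named("train_loss") = train_loss);
  if (bidirectional) {
    out["Wb"] = Pb.W; out["Ub"] = Pb.U; out["bb"] = arma::vec(Pb.b.t());
  }
  if (attention) {
    out["Wa"] = hd.Wa; out["ba"] = arma::vec(hd.ba.t()); out["va"] = hd.v;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_lstm_predict(const Rcpp::List& model, const arma::imat& X,
                           const arma::vec& lengths, int batch_size = 256) {
  arma::mat E = model["embedding"];
  const bool bidirectional = model["bidirectional"];
  const bool attention = model["attention"];
  const int H = model["hidden"], L = X.n_cols, n = X.n_rows;
  const int D2 = bidirectional ? 2 * H : H;
  DirParams Pf, Pb;
  Pf.W = Rcpp::as<arma::mat>(model["Wf"]);
  Pf.U = Rcpp::as<arma::mat>(model["Uf"]);
  Pf.b = Rcpp::as<arma::vec>(model["bf"]).t();
  if (bidirectional) {
    Pb.W = Rcpp::as<arma::mat>(model["Wb"]);
    Pb.U = Rcpp::as<arma::mat>(model["Ub"]);
    Pb.b = Rcpp::as<arma::vec>(model["bb"]).t();
  }
  Head hd; hd.attention = attention; hd.bidirectional = bidirectional;
  if (attention) {
    hd.Wa = Rcpp::as<arma::mat>(model["Wa"]);
    hd.ba = Rcpp::as<arma::vec>(model["ba"]).t();
    hd.v = Rcpp::as<arma::vec>(model["va"]);
  }
  hd.w_out = Rcpp::as<arma::vec>(model["out_w"]);
  hd.b_out = model["out_b"];

  arma::vec out(n);
  for (int start = 0; start < n; start += batch_size) {
    int B = std::min(batch_size, n - start);
    std::vector<int> rows(B);
    for (int i = 0; i < B; ++i) rows[i] = start + i;
    int T = 1;
    arma::vec len(B);
    for (int i = 0; i < B; ++i) {
      len[i] = std::max(1.0, std::min((double)L, lengths[rows[i]]));
      T = std::max(T, (int)len[i]);
    }
    std::vector<std::vector<int>> cols_f(B, std::vector<int>(T)),
        cols_b(B, std::vector<int>(T));
    for (int i = 0; i < B; ++i)
      for (int t = 0; t < T; ++t) {
        cols_f[i][t] = t;
        cols_b[i][t] = (t < len[i]) ? (int)len[i] - 1 - t : t;
      }
    DirCache cf, cb;
    dir_forward(E, X, rows, cols_f, len, T, Pf, cf);
    if (bidirectional) dir_forward(E, X, rows, cols_b, len, T, Pb, cb);
    arma::vec logits(B);
    if (attention) {
      arma::mat e(B, T, arma::fill::value(-1e30));
      std::vector<arma::mat> hcat(T);
      for (int t = 0; t < T; ++t) {
        hcat[t].set_size(B, D2);
        hcat[t].cols(0, H - 1) = cf.h[t];
        if (bidirectional) {
          for (int i = 0; i < B; ++i) {
            int tb = (int)len[i] - 1 - t;
            if (t < len[i]) hcat[t].row(i).cols(H, D2 - 1) = cb.h[tb].row(i);
            else hcat[t].row(i).cols(H, D2 - 1).zeros();
          }
        }
        arma::mat u = arma::tanh(hcat[t] * hd.Wa + arma::repmat(hd.ba, B, 1));
        arma::vec et = u * hd.v;
        for (int i = 0; i < B; ++i) if (t < len[i]) e(i, t) = et[i];
      }
      arma::mat alpha(B, T);
      for (int i = 0; i < B; ++i) {
        arma::rowvec r = e.row(i);
        double mx = r.max();
        r = arma::exp(r - mx);
        alpha.row(i) = r / arma::accu(r);
      }
      arma::mat ctx(B, D2, arma::fill::zeros);
      for (int t = 0; t < T; ++t)
        ctx += hcat[t].each_col() % alpha.col(t);
      logits = ctx * hd.w_out + hd.b_out;
    } else {
      arma::mat hfin(B, D2);
      hfin.cols(0, H - 1) = cf.h[T - 1];
      if (bidirectional) hfin.cols(H, D2 - 1) = cb.h[T - 1];
      logits = hfin * hd.w_out + hd.b_out;
    }
    for (int i = 0; i < B; ++i) out[start + i] = sigmoid(logits[i]);
  }
  return out;
}
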