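// Recurrent sequence-to-vector regressors (simple RNN / LSTM / GRU,
// optionally bidirectional, 1-3 layers) with Adam, inverted dropout and
// training-loss early stopping; plus the CMAP superposition kernel.
//
// Parameter layout (flat list of matrices, fixed order):
//   for layer l = 1..L, direction d = fwd[, bwd]:
//     Wx (G*H x I_l), Wh (G*H x H), b (G*H x 1)
//   then V (O x F), c (O x 1)
// Gate order within rows: LSTM i,f,g,o; GRU z,r,n.
// GRU uses the variant n = tanh(Wx_n x + b_n + r % (Wh_n h)).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------- utilities

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Spec {
  int cell;        // 0 simple_rnn, 1 lstm, 2 gru
  bool bidir;
  int layers, hidden, input_dim, output_dim;
  double dropout;
};

static Spec parseSpec(const Rcpp::List& s) {
  Spec sp;
  sp.cell = Rcpp::as<int>(s["cell"]);
  sp.bidir = Rcpp::as<bool>(s["bidir"]);
  sp.layers = Rcpp::as<int>(s["layers"]);
  sp.hidden = Rcpp::as<int>(s["hidden"]);
  sp.input_dim = Rcpp::as<int>(s["input_dim"]);
  sp.output_dim = Rcpp::as<int>(s["output_dim"]);
  sp.dropout = Rcpp::as<double>(s["dropout"]);
  return sp;
}

static inline int gatesFor(int cell) {
  return cell == 1 ? 4 : (cell == 2 ? 3 : 1);
}

typedef std::vector<mat> Params;

static Params unpack(const Rcpp::List& params) {
  Params P;
  for (R_xlen_t i = 0; i < params.size(); ++i)
    P.push_back(Rcpp::as<mat>(params[i]));
  return P;
}

static Rcpp::List pack(const Params& P, const Rcpp::List& tmplNames) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) out[i] = Rcpp::wrap(P[i]);
  out.attr("names") = tmplNames.attr("names");
  return out;
}

// ------------------------------------------------------------- one sequence
// caches for BPTT over a single direction, in processing order

struct Cache {
  cube H;   // hidden x B x T
  cube A;   // gates*hidden x B x T (activated gates; unused for simple)
  cube C;   // lstm: cell state; gru: q = Wh_n h_prev; unused for simple
};

static void forward_seq(int cell, const mat& Wx, const mat& Wh,
                        const mat& b, const cube& X, Cache& cc,
                        bool keep) {
  const int H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  const int G = gatesFor(cell);
  cc.H.set_size(H, B, T);
  if (keep && cell != 0) {
    cc.A.set_size(G * H, B, T);
    cc.C.set_size(H, B, T);
  }
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  const vec bv = b.col(0);
  for (int t = 0; t < T; ++t) {
    const mat& x = X.slice(t);
    if (cell == 1) {                                        // LSTM
      mat a = Wx * x + Wh * h;
      a.each_col() += bv;
      mat i = sigm(a.rows(0, H - 1));
      mat f = sigm(a.rows(H, 2 * H - 1));
      mat g = tanh(a.rows(2 * H, 3 * H - 1));
      mat o = sigm(a.rows(3 * H, 4 * H - 1));
      c = f % c + i % g;
      h = o % tanh(c);
      if (keep) {
        cc.A.slice(t) = join_cols(join_cols(i, f), join_cols(g, o));
        cc.C.slice(t) = c;
      }
    } else if (cell == 2) {                                 // GRU
      mat azr = Wx.rows(0, 2 * H - 1) * x + Wh.rows(0, 2 * H - 1) * h;
      azr.each_col() += bv.subvec(0, 2 * H - 1);
      mat z = sigm(azr.rows(0, H - 1));
      mat r = sigm(azr.rows(H, 2 * H - 1));
      mat q = Wh.rows(2 * H, 3 * H - 1) * h;
      mat an = Wx.rows(2 * H, 3 * H - 1) * x + r % q;
      an.each_col() += bv.subvec(2 * H, 3 * H - 1);
      mat n = tanh(an);
      h = z % h + (1.0 - z) % n;
      if (keep) {
        cc.A.slice(t) = join_cols(join_cols(z, r), n);
        cc.C.slice(t) = q;
      }
    } else {                                                // simple RNN
      mat a = Wx * x + Wh * h;
      a.each_col() += bv;
      h = tanh(a);
    }
    cc.H.slice(t) = h;
  }
}

// backward over one direction; dH = gradient wrt cc.H (processing order).
// accumulates into gWx/gWh/gb; returns gradient wrt X in dX.
static void backward_seq(int cell, const mat& Wx, const mat& Wh,
                         const cube& X, const Cache& cc, const cube& dH,
                         cube& dX, mat& gWx, mat& gWh, mat& gb) {
  const int H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  dX.set_size(X.n_rows, B, T);
  mat carry_h(H, B, fill::zeros), carry_c(H, B, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dH.slice(t) + carry_h;
    const mat& x = X.slice(t);
    mat h_prev = (t > 0) ? cc.H.slice(t - 1) : mat(H, B, fill::zeros);
    if (cell == 1) {                                        // LSTM
      const mat& A = cc.A.slice(t);
      mat i = A.rows(0, H - 1), f = A.rows(H, 2 * H - 1);
      mat g = A.rows(2 * H, 3 * H - 1), o = A.rows(3 * H, 4 * H - 1);
      mat c_prev = (t > 0) ? cc.C.slice(t - 1) : mat(H, B, fill::zeros);
      mat tc = tanh(cc.C.slice(t));
      mat dc = carry_c + dh % o % (1.0 - tc % tc);
      mat da_o = dh % tc % o % (1.0 - o);
      mat da_i = dc % g % i % (1.0 - i);
      mat da_f = dc % c_prev % f % (1.0 - f);
      mat da_g = dc % i % (1.0 - g % g);
      mat da = join_cols(join_cols(da_i, da_f), join_cols(da_g, da_o));
      gWx += da * x.t();
      gWh += da * h_prev.t();
      gb += sum(da, 1);
      dX.slice(t) = Wx.t() * da;
      carry_h = Wh.t() * da;
      carry_c = dc % f;
    } else if (cell == 2) {                                 // GRU
      const mat& A = cc.A.slice(t);
      mat z = A.rows(0, H - 1), r = A.rows(H, 2 * H - 1);
      mat n = A.rows(2 * H, 3 * H - 1);
      const mat& q = cc.C.slice(t);
      mat dz = dh % (h_prev - n);
      mat dn = dh % (1.0 - z);
      mat carry_base = dh % z;
      mat da_n = dn % (1.0 - n % n);
      mat dr = da_n % q;
      mat dq = da_n % r;
      mat da_z = dz % z % (1.0 - z);
      mat da_r = dr % r % (1.0 - r);
      mat da_zr = join_cols(da_z, da_r);
      gWx.rows(0, 2 * H - 1) += da_zr * x.t();
      gWx.rows(2 * H, 3 * H - 1) += da_n * x.t();
      gWh.rows(0, 2 * H - 1) += da_zr * h_prev.t();
      gWh.rows(2 * H, 3 * H - 1) += dq * h_prev.t();
      gb.rows(0, 2 * H - 1) += sum(da_zr, 1);
      gb.rows(2 * H, 3 * H - 1) += sum(da_n, 1);
      dX.slice(t) = Wx.t() * join_cols(da_zr, da_n);
      carry_h = carry_base + Wh.rows(0, 2 * H - 1).t() * da_zr +
        Wh.rows(2 * H, 3 * H - 1).t() * dq;
    } else {                                                // simple RNN
      const mat& h = cc.H.slice(t);
      mat da = dh % (1.0 - h % h);
      gWx += da * x.t();
      gWh += da * h_prev.t();
      gb += sum(da, 1);
      dX.slice(t) = Wx.t() * da;
      carry_h = Wh.t() * da;
    }
  }
}

static cube reverse_time(const cube& X) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t)
    Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

// --------------------------------------------------------------- full stack

struct LayerState {
  cube in;          // layer input (natural time order)
  cube in_rev;      // reversed copy (bidirectional only)
  Cache fwd, bwd;   // bwd cache is in processing (reversed) order
  cube mask;        // dropout mask on sequence output (intermediate layers)
};

// forward through the recurrent stack; returns the feature matrix (F x B).
// train = TRUE keeps caches and samples dropout masks from rng.
static mat net_forward(const Params& P, const Spec& sp, const cube& X0,
                       bool train, std::mt19937_64& rng,
                       std::vector<LayerState>& st, mat& featMask) {
  const int dirs = sp.bidir ? 2 : 1;
  const int T = X0.n_slices, B = X0.n_cols, H = sp.hidden;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keepP = 1.0 - sp.dropout;
  st.resize(sp.layers);
  cube cur = X0;
  mat feat;
  for (int l = 0; l < sp.layers; ++l) {
    LayerState& L = st[l];
    if (train) L.in = cur;
    const mat& WxF = P[3 * (l * dirs + 0) + 0];
    const mat& WhF = P[3 * (l * dirs + 0) + 1];
    const mat& bF  = P[3 * (l * dirs + 0) + 2];
    forward_seq(sp.cell, WxF, WhF, bF, cur, L.fwd, train);
    if (sp.bidir) {
      cube rev = reverse_time(cur);
      if (train) L.in_rev = rev;
      const mat& WxB = P[3 * (l * dirs + 1) + 0];
      const mat& WhB = P[3 * (l * dirs + 1) + 1];
      const mat& bB  = P[3 * (l * dirs + 1) + 2];
      forward_seq(sp.cell, WxB, WhB, bB, rev, L.bwd, train);
    }
    const bool last = (l == sp.layers - 1);
    if (last) {
      // temporal mean-pooled readout of the final layer's sequence
      feat.zeros(dirs * H, B);
      for (int t = 0; t < T; ++t) {
        feat.rows(0, H - 1) += L.fwd.H.slice(t);
        if (sp.bidir) feat.rows(H, 2 * H - 1) += L.bwd.H.slice(t);
      }
      feat /= double(T);
    } else {
      cube out(dirs * H, B, T);
      for (int t = 0; t < T; ++t) {
        out.slice(t) = sp.bidir
          ? join_cols(L.fwd.H.slice(t), L.bwd.H.slice(T - 1 - t))
          : mat(L.fwd.H.slice(t));
      }
      if (train && sp.dropout > 0) {
        L.mask.set_size(out.n_rows, B, T);
        for (uword k = 0; k < L.mask.n_elem; ++k)
          L.mask(k) = (unif(rng) < keepP) ? 1.0 / keepP : 0.0;
        out %= L.mask;
      }
      cur = out;
    }
  }
  if (train && sp.dropout > 0) {
    featMask.set_size(feat.n_rows, feat.n_cols);
    for (uword k = 0; k < featMask.n_elem; ++k)
      featMask(k) = (unif(rng) < keepP) ? 1.0 / keepP : 0.0;
    feat %= featMask;
  } else {
    featMask.reset();
  }
  return feat;
}

// backward through the stack; dFeat is the gradient wrt the (dropped)
// feature matrix. grads has the same layout as P.
static void net_backward(const Params& P, const Spec& sp,
                         std::vector<LayerState>& st, const mat& dFeatIn,
                         const mat& featMask, Params& grads) {
  const int dirs = sp.bidir ? 2 : 1;
  const int H = sp.hidden;
  mat dFeat = featMask.n_elem ? mat(dFeatIn % featMask) : dFeatIn;
  cube dOut;  // gradient wrt current layer's sequence output
  for (int l = sp.layers - 1; l >= 0; --l) {
    LayerState& L = st[l];
    const int T = L.in.n_slices, B = L.in.n_cols;
    cube dHf(H, B, T, fill::zeros), dHb;
    if (sp.bidir) dHb = cube(H, B, T, fill::zeros);
    if (l == sp.layers - 1) {
      mat dtop = dFeat.rows(0, H - 1) / double(T);
      for (int t = 0; t < T; ++t) dHf.slice(t) = dtop;
      if (sp.bidir) {
        mat dbot = dFeat.rows(H, 2 * H - 1) / double(T);
        for (int t = 0; t < T; ++t) dHb.slice(t) = dbot;
      }
    } else {
      if (L.mask.n_elem) dOut %= L.mask;
      for (int t = 0; t < T; ++t) {
        dHf.slice(t) = dOut.slice(t).rows(0, H - 1);
        if (sp.bidir)
          dHb.slice(T - 1 - t) = dOut.slice(t).rows(H, 2 * H - 1);
      }
    }
    const int iF = 3 * (l * dirs + 0);
    cube dXf;
    backward_seq(sp.cell, P[iF], P[iF + 1], L.in, L.fwd, dHf, dXf,
                 grads[iF], grads[iF + 1], grads[iF + 2]);
    if (sp.bidir) {
      const int iB = 3 * (l * dirs + 1);
      cube dXr;
      backward_seq(sp.cell, P[iB], P[iB + 1], L.in_rev, L.bwd, dHb, dXr,
                   grads[iB], grads[iB + 1], grads[iB + 2]);
      dXf += reverse_time(dXr);
    }
    dOut = dXf;  // becomes gradient wrt layer l-1's (dropped) output
  }
}

// ------------------------------------------------------------------- public

// [[Rcpp::export]]
Rcpp::List rnn_init_cpp(Rcpp::List spec, int seed) {
  Spec sp = parseSpec(spec);
  const int dirs = sp.bidir ? 2 : 1, G = gatesFor(sp.cell), H = sp.hidden;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1u);
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  Rcpp::List out;
  Rcpp::CharacterVector nms;
  for (int l = 0; l < sp.layers; ++l) {
    const int I = (l == 0) ? sp.input_dim : dirs * H;
    for (int d = 0; d < dirs; ++d) {
      double lim = std::sqrt(6.0 / (I + G * H));
      mat Wx(G * H, I);
      for (uword k = 0; k < Wx.n_elem; ++k) Wx(k) = lim * unif(rng);
      mat Wh(G * H, H);
      for (int g = 0; g < G; ++g) {       // orthogonal recurrent blocks
        mat Aij(H, H);
        for (uword k = 0; k < Aij.n_elem; ++k) Aij(k) = norm(rng);
        mat Q, Rr;
        qr_econ(Q, Rr, Aij);
        Q *= diagmat(sign(Rr.diag()));
        Wh.rows(g * H, (g + 1) * H - 1) = Q;
      }
      mat b(G * H, 1, fill::zeros);
      if (sp.cell == 1) b.rows(H, 2 * H - 1).fill(1.0);  // forget-gate bias
      std::string tag = "_l" + std::to_string(l + 1) +
        (d == 0 ? "_fwd" : "_bwd");
      out.push_back(Rcpp::wrap(Wx), "Wx" + tag);
      out.push_back(Rcpp::wrap(Wh), "Wh" + tag);
      out.push_back(Rcpp::wrap(b), "b" + tag);
    }
  }
  const int F = dirs * H;
  double lim = std::sqrt(6.0 / (F + sp.output_dim));
  mat V(sp.output_dim, F);
  for (uword k = 0; k < V.n_elem; ++k) V(k) = lim * unif(rng);
  out.push_back(Rcpp::wrap(V), "V");
  out.push_back(Rcpp::wrap(mat(sp.output_dim, 1, fill::zeros)), "c");
  return out;
}

// build the (1 x B x T) input cube for rows `idx` of X (N x T)
static cube make_input(const mat& X, const uvec& idx) {
  cube X0(1, idx.n_elem, X.n_cols);
  for (uword t = 0; t < X.n_cols; ++t)
    for (uword b = 0; b < idx.n_elem; ++b)
      X0(0, b, t) = X(idx[b], t);
  return X0;
}

static mat predict_all(const Params& P, const Spec& sp, const mat& X,
                       int chunk) {
  const int N = X.n_rows;
  mat out(N, sp.output_dim);
  std::mt19937_64 dummy(0);
  std::vector<LayerState> st;
  mat featMask;
  const mat& V = P[P.size() - 2];
  const vec cv = P[P.size() - 1].col(0);
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = regspace<uvec>(s, e - 1);
    cube X0 = make_input(X, idx);
    mat feat = net_forward(P, sp, X0, false, dummy, st, featMask);
    mat yhat = V * feat;
    yhat.each_col() += cv;
    out.rows(s, e - 1) = yhat.t();
  }
  return out;
}

// [[Rcpp::export]]
arma::mat rnn_predict_cpp(Rcpp::List params, Rcpp::List spec, arma::mat X,
                          int chunk = 512) {
  Params P = unpack(params);
  Spec sp = parseSpec(spec);
  return predict_all(P, sp, X, chunk);
}

static double argmax_acc(const mat& pred, const mat& truth) {
  // rows = cases; first-index tie-breaking on both sides
  int hit = 0;
  for (uword i = 0; i < pred.n_rows; ++i) {
    uword pa = pred.row(i).index_max();
    uword ta = truth.row(i).index_max();
    if (pa == ta) ++hit;
  }
  return double(hit) / double(pred.n_rows);
}

// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(Rcpp::List params, Rcpp::List spec,
                         arma::mat Xtr, arma::mat Ytr,
                         arma::mat Xva, arma::mat Yva,
                         int max_epochs, int batch_size, double lr,
                         int patience, int seed, bool verbose) {
  Params P = unpack(params);
  Spec sp = parseSpec(spec);
  const int N = Xtr.n_rows, O = sp.output_dim;
  if (N < 1) Rcpp::stop("empty training set");
  if ((int)Ytr.n_cols != O) Rcpp::stop("label dimension mismatch");
  if (Ytr.n_rows != (uword)N) Rcpp::stop("waveform/label count mismatch");

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL
                      + 1442695040888963407ULL);
  // Adam state
  Params M, Vv;
  for (size_t i = 0; i < P.size(); ++i) {
    M.push_back(mat(P[i].n_rows, P[i].n_cols, fill::zeros));
    Vv.push_back(mat(P[i].n_rows, P[i].n_cols, fill::zeros));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long step = 0;

  std::vector<double> hTL, hTA, hVL, hVA;
  double best = datum::inf;
  int wait = 0, stopped = max_epochs;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  const bool hasVal = Xva.n_rows > 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double lossSum = 0.0, accSum = 0.0;
    long seen = 0;
    for (int s = 0; s < N; s += batch_size) {
      Rcpp::checkUserInterrupt();
      int e = std::min(N, s + batch_size);
      int B = e - s;
      uvec idx(B);
      for (int k = 0; k < B; ++k) idx[k] = order[s + k];
      cube X0 = make_input(Xtr, idx);
      mat Y(O, B);
      for (int k = 0; k < B; ++k) Y.col(k) = Ytr.row(idx[k]).t();

      std::vector<LayerState> st;
      mat featMask;
      mat feat = net_forward(P, sp, X0, true, rng, st, featMask);
      const mat& Vd = P[P.size() - 2];
      mat yhat = Vd * feat;
      yhat.each_col() += P[P.size() - 1].col(0);
      mat diff = yhat - Y;
      double loss = accu(diff % diff) / double(O * B);
      lossSum += loss * B;
      accSum += argmax_acc(yhat.t(), Y.t()) * B;
      seen += B;

      Params G;
      for (size_t i = 0; i < P.size(); ++i)
        G.push_back(mat(P[i].n_rows, P[i].n_cols, fill::zeros));
      mat dyhat = (2.0 / double(O * B)) * diff;
      G[P.size() - 2] = dyhat * feat.t();
      G[P.size() - 1] = sum(dyhat, 1);
      mat dFeat = Vd.t() * dyhat;
      net_backward(P, sp, st, dFeat, featMask, G);

      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, step)) /
        (1.0 - std::pow(b1, step));
      for (size_t i = 0; i < P.size(); ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        Vv[i] = b2 * Vv[i] + (1.0 - b2) * (G[i] % G[i]);
        P[i] -= corr * M[i] / (sqrt(Vv[i]) + eps);
      }
    }
    double trLoss = lossSum / seen, trAcc = accSum / seen;
    double vaLoss = datum::nan, vaAcc = datum::nan;
    if (hasVal) {
      mat pv = predict_all(P, sp, Xva, 512);
      mat dv = pv - Yva;
      vaLoss = accu(dv % dv) / double(dv.n_elem);
      vaAcc = argmax_acc(pv, Yva);
    }
    hTL.push_back(trLoss); hTA.push_back(trAcc);
    hVL.push_back(vaLoss); hVA.push_back(vaAcc);
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch << " loss " << trLoss
                  << " acc " << trAcc << " val_loss " << vaLoss
                  << " val_acc " << vaAcc << std::endl;
    if (!std::isfinite(trLoss)) { stopped = epoch; break; }
    if (trLoss < best) {
      best = trLoss;
      wait = 0;
    } else {
      ++wait;
      if (wait >= patience) { stopped = epoch; break; }
    }
    stopped = epoch;
  }

  return Rcpp::List::create(
    Rcpp::Named("params") = pack(P, params),
    Rcpp::Named("train_loss") = hTL,
    Rcpp::Named("train_acc") = hTA,
    Rcpp::Named("val_loss") = hVL,
    Rcpp::Named("val_acc") = hVA,
    Rcpp::Named("stopped_epoch") = stopped);
}

// MSE loss and analytic parameter gradients for one batch, dropout
// disabled; used for gradient verification and diagnostics
// [[Rcpp::export]]
Rcpp::List rnn_lossgrad_cpp(Rcpp::List params, Rcpp::List spec,
                            arma::mat X, arma::mat Y) {
  Params P = unpack(params);
  Spec sp = parseSpec(spec);
  sp.dropout = 0.0;
  const int O = sp.output_dim, B = X.n_rows;
  std::mt19937_64 dummy(0);
  std::vector<LayerState> st;
  mat featMask;
  uvec idx = regspace<uvec>(0, B - 1);
  cube X0 = make_input(X, idx);
  mat feat = net_forward(P, sp, X0, true, dummy, st, featMask);
  const mat& V = P[P.size() - 2];
  mat yhat = V * feat;
  yhat.each_col() += P[P.size() - 1].col(0);
  mat diff = yhat - Y.t();
  double loss = accu(diff % diff) / double(O * B);
  Params G;
  for (size_t i = 0; i < P.size(); ++i)
    G.push_back(mat(P[i].n_rows, P[i].n_cols, fill::zeros));
  mat dyhat = (2.0 / double(O * B)) * diff;
  G[P.size() - 2] = dyhat * feat.t();
  G[P.size() - 1] = sum(dyhat, 1);
  net_backward(P, sp, st, V.t() * dyhat, featMask, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(G, params));
}

// ------------------------------------------------------- CMAP superposition

// sum one template copy per conducting axon, shifted by `steps` grid
// samples, into an n_out-sample window (out-of-window samples truncated)
// [[Rcpp::export]]
arma::vec cmap_superpose(Rcpp::IntegerVector steps, arma::vec tmpl,
                         int n_out) {
  vec out(n_out, fill::zeros);
  const int T = tmpl.n_elem;
  for (int a = 0; a < steps.size(); ++a) {
    const int s = steps[a];
    const int j0 = std::max(0, -s);
    const int j1 = std::min(T, n_out - s);
    for (int j = j0; j < j1; ++j) out[j + s] += tmpl[j];
  }
  return out;
}
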