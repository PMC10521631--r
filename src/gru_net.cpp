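// Bidirectional GRU residual network: embedding -> two bidirectional GRU
// layers -> dense head with charge one-hot -> scalar residual CCS.
//
// Implemented from scratch (forward pass, backpropagation through time,
// Adam, MAE objective) so training is single-threaded and bit-reproducible
// for a given seed. The GRU uses the dual-bias ("reset after")
// parameterisation, 3*(in*u + u*u + 2u) weights per direction.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::CharacterVector;

static const char* WEIGHT_NAMES[] = {
  "emb",
  "g1f_Wx", "g1f_Wh", "g1f_bx", "g1f_bh",
  "g1b_Wx", "g1b_Wh", "g1b_bx", "g1b_bh",
  "g2f_Wx", "g2f_Wh", "g2f_bx", "g2f_bh",
  "g2b_Wx", "g2b_Wh", "g2b_bx", "g2b_bh",
  "d1_W", "d1_b", "d2_W", "d2_b", "out_W", "out_b"
};
static const int N_W = 23;
enum WIdx { EMB = 0,
  G1F_WX, G1F_WH, G1F_BX, G1F_BH,
  G1B_WX, G1B_WH, G1B_BX, G1B_BH,
  G2F_WX, G2F_WH, G2F_BX, G2F_BH,
  G2B_WX, G2B_WH, G2B_BX, G2B_BH,
  D1_W, D1_B, D2_W, D2_B, OUT_W, OUT_B };

struct Config {
  int V, E, u1, u2, h1, h2, C;
  double dropout;
};

static Config read_config(const List& cfg) {
  Config c;
  c.V = Rcpp::as<int>(cfg["vocab_size"]);
  c.E = Rcpp::as<int>(cfg["embedding_dim"]);
  c.u1 = Rcpp::as<int>(cfg["units1"]);
  c.u2 = Rcpp::as<int>(cfg["units2"]);
  c.h1 = Rcpp::as<int>(cfg["dense1"]);
  c.h2 = Rcpp::as<int>(cfg["dense2"]);
  c.C = Rcpp::as<int>(cfg["max_charge"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  return c;
}

static std::vector<mat> read_weights(const List& wl) {
  std::vector<mat> W(N_W);
  for (int i = 0; i < N_W; ++i) {
    Rcpp::RObject obj = wl[WEIGHT_NAMES[i]];
    if (Rf_isMatrix(obj)) {
      W[i] = Rcpp::as<mat>(obj);
    } else {
      vec v = Rcpp::as<vec>(obj);
      W[i] = mat(v);  // column vector
    }
  }
  return W;
}

static List weights_to_list(const std::vector<mat>& W) {
  List out(N_W);
  CharacterVector nms(N_W);
  for (int i = 0; i < N_W; ++i) {
    out[i] = Rcpp::wrap(W[i]);
    nms[i] = WEIGHT_NAMES[i];
  }
  out.attr("names") = nms;
  return out;
}

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// Caches for one direction of one GRU layer over one sequence.
struct DirCache {
  mat H, Z, R, N, HN;  // u x L, column s = processing step s
};

// Forward one direction over input X (in x L). reverse=true processes
// positions L-1..0. Hidden state starts at zero.
static void dir_forward(const mat& Wx, const mat& Wh,
                        const vec& bx, const vec& bh,
                        const mat& X, bool reverse, DirCache& c) {
  const int L = X.n_cols;
  const int u = Wh.n_cols;
  c.H.set_size(u, L); c.Z.set_size(u, L); c.R.set_size(u, L);
  c.N.set_size(u, L); c.HN.set_size(u, L);
  vec h = zeros<vec>(u);
  for (int s = 0; s < L; ++s) {
    const int pos = reverse ? (L - 1 - s) : s;
    vec pi = Wx * X.col(pos) + bx;
    vec ph = Wh * h + bh;
    vec z = sigmoid(pi.subvec(0, u - 1) + ph.subvec(0, u - 1));
    vec r = sigmoid(pi.subvec(u, 2 * u - 1) + ph.subvec(u, 2 * u - 1));
    vec hn = ph.subvec(2 * u, 3 * u - 1);
    vec n = tanh(pi.subvec(2 * u, 3 * u - 1) + r % hn);
    h = z % h + (1.0 - z) % n;
    c.H.col(s) = h; c.Z.col(s) = z; c.R.col(s) = r;
    c.N.col(s) = n; c.HN.col(s) = hn;
  }
}

// Backward one direction. dH_ext (u x L) is the external gradient on this
// direction's output at each *position*. Accumulates weight grads and adds
// input gradients into dX.
static void dir_backward(const mat& Wx, const mat& Wh,
                         const mat& X, bool reverse, const DirCache& c,
                         const mat& dH_ext,
                         mat& gWx, mat& gWh, vec& gbx, vec& gbh, mat& dX) {
  const int L = X.n_cols;
  const int u = Wh.n_cols;
  vec carry = zeros<vec>(u);
  for (int s = L - 1; s >= 0; --s) {
    const int pos = reverse ? (L - 1 - s) : s;
    vec hprev = (s == 0) ? zeros<vec>(u) : vec(c.H.col(s - 1));
    vec z = c.Z.col(s), r = c.R.col(s), n = c.N.col(s), hn = c.HN.col(s);
    vec dh = dH_ext.col(pos) + carry;
    vec dz = dh % (hprev - n) % z % (1.0 - z);
    vec dn = dh % (1.0 - z) % (1.0 - n % n);
    vec dr = dn % hn % r % (1.0 - r);
    vec dpre_i = join_cols(dz, join_cols(dr, dn));
    vec dpre_h = join_cols(dz, join_cols(dr, vec(dn % r)));
    gWx += dpre_i * X.col(pos).t();
    gWh += dpre_h * hprev.t();
    gbx += dpre_i;
    gbh += dpre_h;
    dX.col(pos) += Wx.t() * dpre_i;
    carry = Wh.t() * dpre_h + dh % z;
  }
}

struct SeqData {
  std::vector<uvec> ids;
  ivec charge;
  vec y;
};

static SeqData read_seqdata(const List& seqs, const IntegerVector& charge,
                            const NumericVector& y) {
  SeqData d;
  d.ids.resize(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    uvec u(s.size());
    for (int j = 0; j < s.size(); ++j) u[j] = (unsigned) s[j];
    d.ids[i] = u;
  }
  d.charge = Rcpp::as<ivec>(charge);
  d.y = Rcpp::as<vec>(y);
  return d;
}

// Full forward for one sequence; when grads != nullptr also runs the
// backward pass for the MAE objective and accumulates gradients. mask is
// the dropout mask on the first dense layer (empty = no dropout).
static double run_sample(const Config& cfg, const std::vector<mat>& W,
                         const uvec& ids, int charge,
                         const vec& mask, double keep,
                         double target, bool train,
                         std::vector<mat>* grads) {
  const int L = ids.n_elem;
  mat X1(cfg.E, L);
  for (int t = 0; t < L; ++t) X1.col(t) = W[EMB].row(ids[t]).t();

  DirCache c1f, c1b, c2f, c2b;
  dir_forward(W[G1F_WX], W[G1F_WH], W[G1F_BX].col(0), W[G1F_BH].col(0), X1, false, c1f);
  dir_forward(W[G1B_WX], W[G1B_WH], W[G1B_BX].col(0), W[G1B_BH].col(0), X1, true,  c1b);

  mat Y1(2 * cfg.u1, L);
  for (int s = 0; s < L; ++s) {
    Y1.submat(0, s, cfg.u1 - 1, s) = c1f.H.col(s);
    Y1.submat(cfg.u1, L - 1 - s, 2 * cfg.u1 - 1, L - 1 - s) = c1b.H.col(s);
  }

  dir_forward(W[G2F_WX], W[G2F_WH], W[G2F_BX].col(0), W[G2F_BH].col(0), Y1, false, c2f);
  dir_forward(W[G2B_WX], W[G2B_WH], W[G2B_BX].col(0), W[G2B_BH].col(0), Y1, true,  c2b);

  vec f(2 * cfg.u2 + cfg.C, fill::zeros);
  f.subvec(0, cfg.u2 - 1) = c2f.H.col(L - 1);
  f.subvec(cfg.u2, 2 * cfg.u2 - 1) = c2b.H.col(L - 1);
  f[2 * cfg.u2 + (charge - 1)] = 1.0;

  vec a1 = W[D1_W] * f + W[D1_B].col(0);
  a1.transform([](double v) { return v > 0 ? v : 0.0; });
  vec a1d = a1;
  if (train && mask.n_elem > 0) a1d = (a1 % mask) / keep;
  vec a2 = W[D2_W] * a1d + W[D2_B].col(0);
  a2.transform([](double v) { return v > 0 ? v : 0.0; });
  double pred = dot(W[OUT_W].row(0).t(), a2) + W[OUT_B](0, 0);

  if (grads == nullptr) return pred;
  std::vector<mat>& G = *grads;

  const double diff = pred - target;
  const double dy = (diff > 0) - (diff < 0);  // d|pred-target|/dpred

  G[OUT_W].row(0) += dy * a2.t();
  G[OUT_B](0, 0) += dy;
  vec da2 = dy * W[OUT_W].row(0).t();
  for (uword i = 0; i < da2.n_elem; ++i) if (a2[i] <= 0) da2[i] = 0;
  G[D2_W] += da2 * a1d.t();
  G[D2_B].col(0) += da2;
  vec da1d = W[D2_W].t() * da2;
  vec da1 = (train && mask.n_elem > 0) ? vec((da1d % mask) / keep) : da1d;
  for (uword i = 0; i < da1.n_elem; ++i) if (a1[i] <= 0) da1[i] = 0;
  G[D1_W] += da1 * f.t();
  G[D1_B].col(0) += da1;
  vec df = W[D1_W].t() * da1;

  mat dY1 = zeros<mat>(2 * cfg.u1, L);
  {
    mat dH_ext = zeros<mat>(cfg.u2, L);
    dH_ext.col(L - 1) = df.subvec(0, cfg.u2 - 1);  // fwd final state @ pos L-1
    vec gbx = G[G2F_BX].col(0), gbh = G[G2F_BH].col(0);
    dir_backward(W[G2F_WX], W[G2F_WH], Y1, false, c2f, dH_ext,
                 G[G2F_WX], G[G2F_WH], gbx, gbh, dY1);
    G[G2F_BX].col(0) = gbx; G[G2F_BH].col(0) = gbh;
  }
  {
    mat dH_ext = zeros<mat>(cfg.u2, L);
    dH_ext.col(0) = df.subvec(cfg.u2, 2 * cfg.u2 - 1);  // bwd final @ pos 0
    vec gbx = G[G2B_BX].col(0), gbh = G[G2B_BH].col(0);
    dir_backward(W[G2B_WX], W[G2B_WH], Y1, true, c2b, dH_ext,
                 G[G2B_WX], G[G2B_WH], gbx, gbh, dY1);
    G[G2B_BX].col(0) = gbx; G[G2B_BH].col(0) = gbh;
  }

  mat dX1 = zeros<mat>(cfg.E, L);
  {
    mat dH_ext = dY1.rows(0, cfg.u1 - 1);
    vec gbx = G[G1F_BX].col(0), gbh = G[G1F_BH].col(0);
    dir_backward(W[G1F_WX], W[G1F_WH], X1, false, c1f, dH_ext,
                 G[G1F_WX], G[G1F_WH], gbx, gbh, dX1);
    G[G1F_BX].col(0) = gbx; G[G1F_BH].col(0) = gbh;
  }
  {
    mat dH_ext = dY1.rows(cfg.u1, 2 * cfg.u1 - 1);
    vec gbx = G[G1B_BX].col(0), gbh = G[G1B_BH].col(0);
    dir_backward(W[G1B_WX], W[G1B_WH], X1, true, c1b, dH_ext,
                 G[G1B_WX], G[G1B_WH], gbx, gbh, dX1);
    G[G1B_BX].col(0) = gbx; G[G1B_BH].col(0) = gbh;
  }
  for (int t = 0; t < L; ++t) G[EMB].row(ids[t]) += dX1.col(t).t();

  return pred;
}

static double eval_mae(const Config& cfg, const std::vector<mat>& W,
                       const SeqData& d) {
  double s = 0;
  vec empty;
  for (size_t i = 0; i < d.ids.size(); ++i) {
    double p = run_sample(cfg, W, d.ids[i], d.charge[i], empty, 1.0,
                          0.0, false, nullptr);
    s += std::abs(p - d.y[i]);
  }
  return s / d.ids.size();
}

// [[Rcpp::export]]
NumericVector cpp_predict_gru(List weights, List config, List seqs,
                              IntegerVector charges) {
  Config cfg = read_config(config);
  std::vector<mat> W = read_weights(weights);
  NumericVector out(seqs.size());
  vec empty;
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    uvec ids(s.size());
    for (int j = 0; j < s.size(); ++j) ids[j] = (unsigned) s[j];
    out[i] = run_sample(cfg, W, ids, charges[i], empty, 1.0, 0.0, false,
                        nullptr);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train_gru(List weights, List config,
                   List train_seqs, IntegerVector train_charge,
                   NumericVector train_y,
                   List val_seqs, IntegerVector val_charge,
                   NumericVector val_y,
                   double lr, int batch_size, int max_epochs,
                   int patience, double lr_factor, int seed) {
  Config cfg = read_config(config);
  std::vector<mat> W = read_weights(weights);
  SeqData tr = read_seqdata(train_seqs, train_charge, train_y);
  SeqData va = read_seqdata(val_seqs, val_charge, val_y);
  const int n = tr.ids.size();

  std::vector<mat> G(N_W), M(N_W), Vv(N_W);
  for (int i = 0; i < N_W; ++i) {
    G[i] = zeros<mat>(W[i].n_rows, W[i].n_cols);
    M[i] = zeros<mat>(W[i].n_rows, W[i].n_cols);
    Vv[i] = zeros<mat>(W[i].n_rows, W[i].n_cols);
  }

  std::mt19937 rng((unsigned) seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - cfg.dropout;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  std::vector<double> h_train, h_val, h_lr;
  std::vector<mat> best_W = W;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, phase = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double train_abs = 0;
    int done = 0;
    while (done < n) {
      int bs = std::min(batch_size, n - done);
      for (int i = 0; i < N_W; ++i) G[i].zeros();
      for (int k = 0; k < bs; ++k) {
        int idx = order[done + k];
        vec mask;
        if (cfg.dropout > 0) {
          mask.set_size(cfg.h1);
          for (int j = 0; j < cfg.h1; ++j)
            mask[j] = unif(rng) < keep ? 1.0 : 0.0;
        }
        double p = run_sample(cfg, W, tr.ids[idx], tr.charge[idx], mask,
                              keep, tr.y[idx], true, &G);
        train_abs += std::abs(p - tr.y[idx]);
      }
      // average grads over batch, Adam step
      adam_t++;
      const double bc1 = 1.0 - std::pow(beta1, (double) adam_t);
      const double bc2 = 1.0 - std::pow(beta2, (double) adam_t);
      for (int i = 0; i < N_W; ++i) {
        mat g = G[i] / (double) bs;
        M[i] = beta1 * M[i] + (1.0 - beta1) * g;
        Vv[i] = beta2 * Vv[i] + (1.0 - beta2) * (g % g);
        W[i] -= lr * (M[i] / bc1) / (sqrt(Vv[i] / bc2) + eps);
      }
      done += bs;
    }
    double train_mae = train_abs / n;
    double val_mae = eval_mae(cfg, W, va);
    h_train.push_back(train_mae);
    h_val.push_back(val_mae);
    h_lr.push_back(lr);

    if (val_mae < best_val - 1e-12) {
      best_val = val_mae;
      best_W = W;
      best_epoch = epoch;
      wait = 0;
    } else {
      wait++;
      if (wait >= patience) {
        if (phase == 0) {
          lr *= lr_factor;
          phase = 1;
          wait = 0;
        } else {
          break;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    Rcpp::Named("weights") = weights_to_list(best_W),
    Rcpp::Named("final_weights") = weights_to_list(W),
    Rcpp::Named("train_mae") = Rcpp::wrap(h_train),
    Rcpp::Named("val_mae") = Rcpp::wrap(h_val),
    Rcpp::Named("lr") = Rcpp::wrap(h_lr),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_mae") = best_val);
}
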