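// Training core: forward pass, analytic backpropagation and AdamW for the
// gated entity-aware transformer classifier. Mirrors the R-level operations
// exactly (eval-mode outputs agree to numerical precision); kept in C++ so
// that full training runs are cheap on a single CPU.
//
// Parameter layout (must match init_params() ordering):
//   [0] tok_emb [1] pos_emb [2] seg_emb [3] ent_emb [4] emb_ln_g [5] emb_ln_b
//   per layer l (base 6 + 18*l):
//     Wq bq Wk bk Wv bv Wg bg Wo bo ln1_g ln1_b W1 b1 W2 b2 ln2_g ln2_b
//   last two: cls_W cls_b
// Hidden states are rows (n x d); head h occupies columns
// [h*dk, (h+1)*dk) of the d x d projections.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

static const double LN_EPS = 1e-12;

struct Config {
  int L, H, d, dk, C;
  bool use_ent;
  std::vector<int> entity_aware;  // 0/1 per layer
  double dropout, attn_dropout;
};

static Config parse_cfg(const List& cfg) {
  Config c;
  c.L = as<int>(cfg["L"]); c.H = as<int>(cfg["H"]); c.d = as<int>(cfg["d"]);
  c.C = as<int>(cfg["C"]); c.dk = c.d / c.H;
  c.use_ent = as<bool>(cfg["use_entity_embedding"]);
  c.entity_aware = as<std::vector<int>>(cfg["entity_aware"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.attn_dropout = as<double>(cfg["attn_dropout"]);
  return c;
}

typedef std::vector<mat> Params;

static Params params_from_list(const List& p) {
  Params out(p.size());
  for (int i = 0; i < p.size(); ++i) out[i] = as<mat>(p[i]);
  return out;
}

static List params_to_list(const Params& p, const CharacterVector& names) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = wrap(p[i]);
  out.attr("names") = names;
  return out;
}

static inline int lbase(int l) { return 6 + 18 * l; }
// offsets within a layer block
enum { Wq, bq, Wk, bk, Wv, bv, Wg, bg, Wo, bo, ln1_g, ln1_b,
       W1, b1, W2, b2, ln2_g, ln2_b };

// ---------- primitive forward/backward pieces ----------

struct LNCache { mat xhat; vec inv_sd; };

static mat layer_norm_fwd(const mat& x, const mat& g, const mat& b, LNCache& c) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec sd = arma::sqrt(arma::mean(arma::square(xc), 1) + LN_EPS);
  c.inv_sd = 1.0 / sd;
  c.xhat = xc.each_col() % c.inv_sd;
  mat out = c.xhat.each_row() % g.row(0);
  out.each_row() += b.row(0);
  return out;
}

static mat layer_norm_bwd(const mat& dy, const mat& g, const LNCache& c,
                          mat& dg, mat& db) {
  dg.row(0) += arma::sum(dy % c.xhat, 0);
  db.row(0) += arma::sum(dy, 0);
  mat dxhat = dy.each_row() % g.row(0);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.inv_sd;
  return dx;
}

// masked softmax over eligible columns; rows with elig_row false (or no
// eligible column) are all-zero
static mat masked_softmax_fwd(const mat& scores, const uvec& elig_row,
                              const uvec& elig_col) {
  int n = scores.n_rows;
  mat S(n, n, arma::fill::zeros);
  arma::uvec cols = arma::find(elig_col);
  if (cols.n_elem == 0) return S;
  for (int i = 0; i < n; ++i) {
    if (!elig_row(i)) continue;
    rowvec z = scores.row(i);
    double m = z(cols(0));
    for (size_t j = 1; j < cols.n_elem; ++j) m = std::max(m, z(cols(j)));
    double tot = 0.0;
    for (size_t j = 0; j < cols.n_elem; ++j) {
      double e = std::exp(z(cols(j)) - m);
      S(i, cols(j)) = e; tot += e;
    }
    for (size_t j = 0; j < cols.n_elem; ++j) S(i, cols(j)) /= tot;
  }
  return S;
}

static mat softmax_bwd(const mat& S, const mat& dS) {
  vec r = arma::sum(dS % S, 1);
  mat dz = S % (dS.each_col() - r);
  return dz;
}

static inline double gelu1(double x) { return 0.5 * x * (1.0 + std::erf(x / M_SQRT2)); }
static inline double dgelu1(double x) {
  double Phi = 0.5 * (1.0 + std::erf(x / M_SQRT2));
  double phi = std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
  return Phi + x * phi;
}

static mat dropout_mask(int n, int m, double rate) {
  mat mask(n, m);
  double keep = 1.0 - rate;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      mask(i, j) = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
  return mask;
}

// ---------- per-sequence caches ----------

struct HeadCache {
  mat S_glob, S_local, fused, drop_mask;  // n x n
};

struct LayerCache {
  mat h_in;            // n x d
  vec gate;            // n
  mat Q, K, V;         // n x d (all heads)
  std::vector<HeadCache> heads;
  mat concat;          // n x d pre-projection
  mat attn_drop;       // n x d residual dropout mask (empty if eval)
  LNCache ln1;
  mat h1;              // n x d after first LN
  mat z1;              // n x 4d pre-GELU
  mat a1;              // n x 4d post-GELU
  mat ffn_drop;        // n x d
  LNCache ln2;
};

struct SeqCache {
  int n;
  mat emb_sum;         // pre-LN embedding sum (not needed for bwd)
  LNCache emb_ln;
  mat h0;              // post-LN (pre-dropout)
  mat emb_drop;        // mask
  std::vector<LayerCache> layers;
  mat h_final;
  rowvec probs;
};

// forward for one sequence; ids are 0-based, length n (padded)
static void seq_forward(const arma::ivec& tok, const arma::ivec& ent,
                        const arma::ivec& seg, const arma::ivec& pad,
                        const Params& P, const Config& cfg, bool train,
                        SeqCache& S) {
  int n = tok.n_elem, d = cfg.d, dk = cfg.dk;
  S.n = n;
  uvec not_pad(n), elig(n);
  for (int i = 0; i < n; ++i) {
    not_pad(i) = pad(i) ? 0u : 1u;
    elig(i) = (ent(i) != 0 && !pad(i)) ? 1u : 0u;
  }
  // embedding
  mat e(n, d);
  for (int i = 0; i < n; ++i) {
    e.row(i) = P[0].row(tok(i)) + P[1].row(i) + P[2].row(seg(i));
    if (cfg.use_ent) e.row(i) += P[3].row(ent(i));
  }
  mat h = layer_norm_fwd(e, P[4], P[5], S.emb_ln);
  S.h0 = h;
  if (train && cfg.dropout > 0) {
    S.emb_drop = dropout_mask(n, d, cfg.dropout);
    h %= S.emb_drop;
  }
  S.layers.resize(cfg.L);
  double scale = 1.0 / std::sqrt((double)dk);
  for (int l = 0; l < cfg.L; ++l) {
    LayerCache& L = S.layers[l];
    int B = lbase(l);
    bool ea = cfg.entity_aware[l] != 0;
    L.h_in = h;
    L.Q = h * P[B + Wq]; L.Q.each_row() += P[B + bq].row(0);
    L.K = h * P[B + Wk]; L.K.each_row() += P[B + bk].row(0);
    L.V = h * P[B + Wv]; L.V.each_row() += P[B + bv].row(0);
    if (ea) {
      vec z = h * P[B + Wg].col(0) + P[B + bg](0, 0);
      L.gate = 1.0 / (1.0 + arma::exp(-z));
    }
    L.heads.resize(cfg.H);
    L.concat.set_size(n, d);
    for (int hd = 0; hd < cfg.H; ++hd) {
      arma::span cs(hd * dk, (hd + 1) * dk - 1);
      mat scores = L.Q.cols(cs) * L.K.cols(cs).t() * scale;
      HeadCache& HC = L.heads[hd];
      HC.S_glob = masked_softmax_fwd(scores, not_pad, not_pad);
      mat fused;
      if (ea) {
        HC.S_local = masked_softmax_fwd(scores, elig, elig);
        fused = HC.S_local.each_col() % L.gate +
                HC.S_glob.each_col() % (1.0 - L.gate);
      } else {
        fused = HC.S_glob;
      }
      if (train && cfg.attn_dropout > 0) {
        HC.drop_mask = dropout_mask(n, n, cfg.attn_dropout);
        HC.fused = fused;  // pre-dropout, for backward through the gate
        fused %= HC.drop_mask;
      } else {
        HC.fused = fused;
      }
      L.concat.cols(cs) = fused * L.V.cols(cs);
    }
    mat a = L.concat * P[B + Wo];
    a.each_row() += P[B + bo].row(0);
    if (train && cfg.dropout > 0) {
      L.attn_drop = dropout_mask(n, d, cfg.dropout);
      a %= L.attn_drop;
    }
    L.h1 = layer_norm_fwd(h + a, P[B + ln1_g], P[B + ln1_b], L.ln1);
    L.z1 = L.h1 * P[B + W1];
    L.z1.each_row() += P[B + b1].row(0);
    L.a1 = L.z1;
    L.a1.transform([](double x) { return gelu1(x); });
    mat f = L.a1 * P[B + W2];
    f.each_row() += P[B + b2].row(0);
    if (train && cfg.dropout > 0) {
      L.ffn_drop = dropout_mask(n, d, cfg.dropout);
      f %= L.ffn_drop;
    }
    h = layer_norm_fwd(L.h1 + f, P[B + ln2_g], P[B + ln2_b], L.ln2);
  }
  S.h_final = h;
  // classifier
  rowvec logits = h.row(0) * P[P.size() - 2];
  logits += P[P.size() - 1].row(0);
  double m = logits.max();
  rowvec ex = arma::exp(logits - m);
  S.probs = ex / arma::accu(ex);
}

// backward for one sequence given dloss/dlogits; accumulates into G
static void seq_backward(const arma::ivec& tok, const arma::ivec& ent,
                         const arma::ivec& seg, const arma::ivec& pad,
                         const Params& P, const Config& cfg, bool train,
                         const SeqCache& S, const rowvec& dlogits, Params& G) {
  int n = S.n, d = cfg.d, dk = cfg.dk;
  int nc = P.size();
  G[nc - 2] += S.h_final.row(0).t() * dlogits;
  G[nc - 1].row(0) += dlogits;
  mat dh(n, d, arma::fill::zeros);
  dh.row(0) = dlogits * P[nc - 2].t();
  double scale = 1.0 / std::sqrt((double)dk);
  for (int l = cfg.L - 1; l >= 0; --l) {
    const LayerCache& L = S.layers[l];
    int B = lbase(l);
    bool ea = cfg.entity_aware[l] != 0;
    // out = LN2(h1 + f)
    mat dsum2 = layer_norm_bwd(dh, P[B + ln2_g], L.ln2, G[B + ln2_g], G[B + ln2_b]);
    mat df = dsum2;
    if (train && cfg.dropout > 0) df %= L.ffn_drop;
    // f = a1 W2 + b2
    G[B + W2] += L.a1.t() * df;
    G[B + b2].row(0) += arma::sum(df, 0);
    mat da1 = df * P[B + W2].t();
    mat dz1 = da1;
    {
      const mat& z = L.z1;
      for (arma::uword j = 0; j < dz1.n_cols; ++j)
        for (arma::uword i = 0; i < dz1.n_rows; ++i)
          dz1(i, j) *= dgelu1(z(i, j));
    }
    G[B + W1] += L.h1.t() * dz1;
    G[B + b1].row(0) += arma::sum(dz1, 0);
    mat dh1 = dsum2 + dz1 * P[B + W1].t();
    // h1 = LN1(h_in + a)
    mat dsum1 = layer_norm_bwd(dh1, P[B + ln1_g], L.ln1, G[B + ln1_g], G[B + ln1_b]);
    mat da = dsum1;
    if (train && cfg.dropout > 0) da %= L.attn_drop;
    // a = concat Wo + bo
    G[B + Wo] += L.concat.t() * da;
    G[B + bo].row(0) += arma::sum(da, 0);
    mat dconcat = da * P[B + Wo].t();
    mat dQ(n, d, arma::fill::zeros), dK(n, d, arma::fill::zeros),
        dV(n, d, arma::fill::zeros);
    vec dgate(n, arma::fill::zeros);
    for (int hd = 0; hd < cfg.H; ++hd) {
      arma::span cs(hd * dk, (hd + 1) * dk - 1);
      const HeadCache& HC = L.heads[hd];
      mat dOk = dconcat.cols(cs);
      mat fused_used = HC.fused;
      if (train && cfg.attn_dropout > 0) fused_used %= HC.drop_mask;
      dV.cols(cs) = fused_used.t() * dOk;
      mat dfused = dOk * L.V.cols(cs).t();
      if (train && cfg.attn_dropout > 0) dfused %= HC.drop_mask;
      mat dscores;
      if (ea) {
        mat dSloc = dfused.each_col() % L.gate;
        mat dSglob = dfused.each_col() % (1.0 - L.gate);
        dgate += arma::sum(dfused % (HC.S_local - HC.S_glob), 1);
        dscores = softmax_bwd(HC.S_local, dSloc) + softmax_bwd(HC.S_glob, dSglob);
      } else {
        dscores = softmax_bwd(HC.S_glob, dfused);
      }
      dscores *= scale;
      dQ.cols(cs) = dscores * L.K.cols(cs);
      dK.cols(cs) = dscores.t() * L.Q.cols(cs);
    }
    mat dh_in = dsum1;  // residual
    if (ea) {
      vec dz = dgate % L.gate % (1.0 - L.gate);
      G[B + Wg].col(0) += L.h_in.t() * dz;
      G[B + bg](0, 0) += arma::accu(dz);
      dh_in += dz * P[B + Wg].col(0).t();
    }
    G[B + Wq] += L.h_in.t() * dQ; G[B + bq].row(0) += arma::sum(dQ, 0);
    G[B + Wk] += L.h_in.t() * dK; G[B + bk].row(0) += arma::sum(dK, 0);
    G[B + Wv] += L.h_in.t() * dV; G[B + bv].row(0) += arma::sum(dV, 0);
    dh_in += dQ * P[B + Wq].t() + dK * P[B + Wk].t() + dV * P[B + Wv].t();
    dh = dh_in;
  }
  // embedding
  if (train && cfg.dropout > 0) dh %= S.emb_drop;
  mat de = layer_norm_bwd(dh, P[4], S.emb_ln, G[4], G[5]);
  for (int i = 0; i < n; ++i) {
    G[0].row(tok(i)) += de.row(i);
    G[1].row(i) += de.row(i);
    G[2].row(seg(i)) += de.row(i);
    if (cfg.use_ent) G[3].row(ent(i)) += de.row(i);
  }
}

// ---------- exported entry points ----------

static arma::ivec mat_row(const IntegerMatrix& M, int r, int len) {
  arma::ivec v(len);
  for (int j = 0; j < len; ++j) v(j) = M(r, j);
  return v;
}

// padding is a suffix: true sequence length = index of first pad flag
static int true_len(const IntegerMatrix& pad, int r) {
  int n = pad.ncol();
  for (int j = 0; j < n; ++j) if (pad(r, j)) return std::max(j, 1);
  return n;
}

// [[Rcpp::export]]
arma::mat cpp_forward(IntegerMatrix tok, IntegerMatrix ent, IntegerMatrix seg,
                      IntegerMatrix pad, List params, List cfg_list) {
  Config cfg = parse_cfg(cfg_list);
  Params P = params_from_list(params);
  int N = tok.nrow();
  mat probs(N, cfg.C);
  SeqCache S;
  for (int r = 0; r < N; ++r) {
    int ln = true_len(pad, r);
    seq_forward(mat_row(tok, r, ln), mat_row(ent, r, ln), mat_row(seg, r, ln),
                mat_row(pad, r, ln), P, cfg, false, S);
    probs.row(r) = S.probs;
  }
  return probs;
}

// [[Rcpp::export]]
List cpp_loss_grad(IntegerMatrix tok, IntegerMatrix ent, IntegerMatrix seg,
                   IntegerMatrix pad, IntegerVector labels, List params,
                   List cfg_list) {
  Config cfg = parse_cfg(cfg_list);
  Params P = params_from_list(params);
  int N = tok.nrow();
  Params G(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
  double loss = 0.0;
  SeqCache S;
  for (int r = 0; r < N; ++r) {
    int ln = true_len(pad, r);
    arma::ivec tk = mat_row(tok, r, ln), en = mat_row(ent, r, ln),
               sg = mat_row(seg, r, ln), pd = mat_row(pad, r, ln);
    seq_forward(tk, en, sg, pd, P, cfg, false, S);
    int y = labels[r];
    loss += -std::log(std::max(S.probs(y), 1e-300));
    rowvec dlogits = S.probs;
    dlogits(y) -= 1.0;
    dlogits /= (double)N;
    seq_backward(tk, en, sg, pd, P, cfg, false, S, dlogits, G);
  }
  loss /= N;
  CharacterVector nms = params.attr("names");
  return List::create(_["loss"] = loss, _["grads"] = params_to_list(G, nms));
}

// macro F1 from 0-based labels/preds
static double macro_f1(const std::vector<int>& y, const std::vector<int>& p, int C) {
  std::vector<double> tp(C, 0), fp(C, 0), fn(C, 0);
  for (size_t i = 0; i < y.size(); ++i) {
    if (y[i] == p[i]) tp[y[i]] += 1;
    else { fp[p[i]] += 1; fn[y[i]] += 1; }
  }
  double f = 0;
  for (int c = 0; c < C; ++c) {
    double pr = (tp[c] + fp[c]) > 0 ? tp[c] / (tp[c] + fp[c]) : 0;
    double rc = (tp[c] + fn[c]) > 0 ? tp[c] / (tp[c] + fn[c]) : 0;
    f += (pr + rc) > 0 ? 2 * pr * rc / (pr + rc) : 0;
  }
  return f / C;
}

// [[Rcpp::export]]
List cpp_train(IntegerMatrix tok, IntegerMatrix ent, IntegerMatrix seg,
               IntegerMatrix pad, IntegerVector labels,
               IntegerMatrix dtok, IntegerMatrix dent, IntegerMatrix dseg,
               IntegerMatrix dpad, IntegerVector dlabels,
               List params, List cfg_list, List train_cfg) {
  Config cfg = parse_cfg(cfg_list);
  Params P = params_from_list(params);
  int N = tok.nrow(), Nd = dtok.nrow();
  int epochs = as<int>(train_cfg["epochs"]);
  int batch = as<int>(train_cfg["batch_size"]);
  double lr0 = as<double>(train_cfg["lr"]);
  double wd = as<double>(train_cfg["weight_decay"]);
  double warmup = as<double>(train_cfg["warmup_ratio"]);
  LogicalVector no_decay = train_cfg["no_decay"];
  double b1m = 0.9, b2m = 0.999, eps = 1e-8;

  Params G(P.size()), M(P.size()), V(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
    M[i] = G[i]; V[i] = G[i];
  }
  long total_steps = (long)epochs * ((N + batch - 1) / batch);
  long warm = std::max(1L, (long)(warmup * total_steps));
  long step = 0;

  std::vector<double> epoch_loss(epochs), dev_f1(epochs);
  Params best = P;
  double best_f1 = -1.0;
  int best_epoch = 0;
  SeqCache S;
  std::vector<int> dy(Nd), dp(Nd);
  for (int i = 0; i < Nd; ++i) dy[i] = dlabels[i];

  for (int ep = 0; ep < epochs; ++ep) {
    // shuffle via R RNG (Fisher-Yates)
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double tot_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int bsz = std::min(batch, N - b0);
      for (size_t i = 0; i < G.size(); ++i) G[i].zeros();
      for (int bi = 0; bi < bsz; ++bi) {
        int r = idx[b0 + bi];
        int ln = true_len(pad, r);
        arma::ivec tk = mat_row(tok, r, ln), en = mat_row(ent, r, ln),
                   sg = mat_row(seg, r, ln), pd = mat_row(pad, r, ln);
        seq_forward(tk, en, sg, pd, P, cfg, true, S);
        int y = labels[r];
        double li = -std::log(std::max(S.probs(y), 1e-300));
        if (!std::isfinite(li)) stop("training diverged: non-finite loss");
        tot_loss += li;
        rowvec dlogits = S.probs;
        dlogits(y) -= 1.0;
        dlogits /= (double)bsz;
        seq_backward(tk, en, sg, pd, P, cfg, true, S, dlogits, G);
      }
      // AdamW step with linear warmup + decay
      ++step;
      double sched = step <= warm ? (double)step / warm
                                  : std::max(0.0, (double)(total_steps - step) /
                                                  std::max(1L, total_steps - warm));
      double lr = lr0 * sched;
      double c1 = 1.0 - std::pow(b1m, (double)step);
      double c2 = 1.0 - std::pow(b2m, (double)step);
      for (size_t i = 0; i < P.size(); ++i) {
        M[i] = b1m * M[i] + (1.0 - b1m) * G[i];
        V[i] = b2m * V[i] + (1.0 - b2m) * (G[i] % G[i]);
        mat upd = (M[i] / c1) / (arma::sqrt(V[i] / c2) + eps);
        if (!no_decay[i]) upd += wd * P[i];
        P[i] -= lr * upd;
      }
      if ((b0 / batch) % 64 == 0) Rcpp::checkUserInterrupt();
    }
    epoch_loss[ep] = tot_loss / N;
    // dev evaluation (eval mode)
    for (int r = 0; r < Nd; ++r) {
      int ln = true_len(dpad, r);
      seq_forward(mat_row(dtok, r, ln), mat_row(dent, r, ln),
                  mat_row(dseg, r, ln), mat_row(dpad, r, ln), P, cfg, false, S);
      dp[r] = (int)S.probs.index_max();
    }
    dev_f1[ep] = macro_f1(dy, dp, cfg.C);
    if (dev_f1[ep] > best_f1) { best_f1 = dev_f1[ep]; best = P; best_epoch = ep + 1; }
  }
  CharacterVector nms = params.attr("names");
  return List::create(
      _["params"] = params_to_list(best, nms),
      _["final_params"] = params_to_list(P, nms),
      _["train_loss"] = epoch_loss,
      _["dev_macro_f1"] = dev_f1,
      _["best_epoch"] = best_epoch);
}
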