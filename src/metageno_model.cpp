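// Compiled forward/backward pass for the chromosome-wise multi-task model.
// Layout conventions: vectors are rows; for a weight W (out x in) the
// projection of a row-vector e is e * W^T, matching the R reference layer.
// All randomness lives in R (parameter init, minibatch order); this code is
// deterministic given its inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

static const int N_CHROM = 22;

enum Mode { CHROM_WISE = 0, GLOBAL_SNP = 1, INDEP_SNP = 2, ONE_HOT = 3 };
enum Kind { TRANSFORMER = 0, LSTM = 1, GRU = 2, CNN = 3, TCN = 4 };

struct Config {
  int mode, kind, V, d, depth, width, heads;
};

static Config parse_config(const List& cfg) {
  Config c;
  c.mode  = as<int>(cfg["mode"]);
  c.kind  = as<int>(cfg["kind"]);
  c.V     = as<int>(cfg["V"]);
  c.d     = as<int>(cfg["d"]);
  c.depth = as<int>(cfg["depth"]);
  c.width = as<int>(cfg["width"]);
  c.heads = as<int>(cfg["heads"]);
  if (c.mode < 0 || c.mode > 3) stop("unknown representation mode");
  if (c.kind < 0 || c.kind > 4) stop("unknown backbone kind");
  if (c.kind == TRANSFORMER && c.depth > 0 && c.d % c.heads != 0)
    stop("embedding dimension must be divisible by head count");
  return c;
}

static mat getm(const List& p, const std::string& name) {
  if (!p.containsElementNamed(name.c_str()))
    stop("missing parameter '%s'", name.c_str());
  return as<mat>(p[name]);
}

struct Params {
  // embedding layer
  mat E, P, Wq, Wk, Wv, null_tok, E_ind;
  // transformer blocks
  std::vector<mat> tWq, tWk, tWv, tWo, tW1, tb1, tW2, tb2;
  // recurrent layers (lstm: 4w rows, gru: 3w rows)
  std::vector<mat> rWx, rWh, rb;
  // conv layers
  std::vector<mat> cW, cb;
  // heads
  mat Wh, bh;
};

static std::string idx_name(const char* stem, int b, const char* field) {
  std::ostringstream ss;
  ss << stem << b << "_" << field;
  return ss.str();
}

static Params load_params(const List& p, const Config& c) {
  Params P;
  if (c.mode == CHROM_WISE || c.mode == GLOBAL_SNP) {
    P.E = getm(p, "E"); P.Wq = getm(p, "Wq");
    P.Wk = getm(p, "Wk"); P.Wv = getm(p, "Wv");
    P.null_tok = getm(p, "null_tok");
    if (c.mode == CHROM_WISE) P.P = getm(p, "P");
  } else if (c.mode == INDEP_SNP) {
    P.E_ind = getm(p, "E_ind");
    P.null_tok = getm(p, "null_tok");
  }
  if (c.kind == TRANSFORMER) {
    for (int b = 0; b < c.depth; ++b) {
      P.tWq.push_back(getm(p, idx_name("tf", b, "Wq")));
      P.tWk.push_back(getm(p, idx_name("tf", b, "Wk")));
      P.tWv.push_back(getm(p, idx_name("tf", b, "Wv")));
      P.tWo.push_back(getm(p, idx_name("tf", b, "Wo")));
      P.tW1.push_back(getm(p, idx_name("tf", b, "W1")));
      P.tb1.push_back(getm(p, idx_name("tf", b, "b1")));
      P.tW2.push_back(getm(p, idx_name("tf", b, "W2")));
      P.tb2.push_back(getm(p, idx_name("tf", b, "b2")));
    }
  } else if (c.kind == LSTM || c.kind == GRU) {
    for (int b = 0; b < c.depth; ++b) {
      P.rWx.push_back(getm(p, idx_name("rnn", b, "Wx")));
      P.rWh.push_back(getm(p, idx_name("rnn", b, "Wh")));
      P.rb.push_back(getm(p, idx_name("rnn", b, "b")));
    }
  } else {
    for (int b = 0; b < c.depth; ++b) {
      P.cW.push_back(getm(p, idx_name("conv", b, "W")));
      P.cb.push_back(getm(p, idx_name("conv", b, "b")));
    }
  }
  P.Wh = getm(p, "Wh"); P.bh = getm(p, "bh");
  return P;
}

// gradients mirror the parameter struct; assembled back into a named List
struct Grads {
  mat E, P, Wq, Wk, Wv, null_tok, E_ind;
  std::vector<mat> tWq, tWk, tWv, tWo, tW1, tb1, tW2, tb2;
  std::vector<mat> rWx, rWh, rb;
  std::vector<mat> cW, cb;
  mat Wh, bh;
  void init_like(const Params& P, const Config& c) {
    if (c.mode == CHROM_WISE || c.mode == GLOBAL_SNP) {
      E.zeros(P.E.n_rows, P.E.n_cols);
      Wq.zeros(P.Wq.n_rows, P.Wq.n_cols);
      Wk.zeros(P.Wk.n_rows, P.Wk.n_cols);
      Wv.zeros(P.Wv.n_rows, P.Wv.n_cols);
      null_tok.zeros(P.null_tok.n_rows, P.null_tok.n_cols);
      if (c.mode == CHROM_WISE) this->P.zeros(P.P.n_rows, P.P.n_cols);
    } else if (c.mode == INDEP_SNP) {
      E_ind.zeros(P.E_ind.n_rows, P.E_ind.n_cols);
      null_tok.zeros(P.null_tok.n_rows, P.null_tok.n_cols);
    }
    auto zl = [](std::vector<mat>& g, const std::vector<mat>& p) {
      g.resize(p.size());
      for (size_t i = 0; i < p.size(); ++i) g[i].zeros(p[i].n_rows, p[i].n_cols);
    };
    zl(tWq, P.tWq); zl(tWk, P.tWk); zl(tWv, P.tWv); zl(tWo, P.tWo);
    zl(tW1, P.tW1); zl(tb1, P.tb1); zl(tW2, P.tW2); zl(tb2, P.tb2);
    zl(rWx, P.rWx); zl(rWh, P.rWh); zl(rb, P.rb);
    zl(cW, P.cW); zl(cb, P.cb);
    Wh.zeros(P.Wh.n_rows, P.Wh.n_cols);
    bh.zeros(P.bh.n_rows, P.bh.n_cols);
  }
  List to_list(const Config& c) const {
    List out;
    if (c.mode == CHROM_WISE || c.mode == GLOBAL_SNP) {
      out["E"] = E; out["Wq"] = Wq; out["Wk"] = Wk; out["Wv"] = Wv;
      out["null_tok"] = null_tok;
      if (c.mode == CHROM_WISE) out["P"] = P;
    } else if (c.mode == INDEP_SNP) {
      out["E_ind"] = E_ind; out["null_tok"] = null_tok;
    }
    for (size_t b = 0; b < tWq.size(); ++b) {
      out[idx_name("tf", b, "Wq")] = tWq[b];
      out[idx_name("tf", b, "Wk")] = tWk[b];
      out[idx_name("tf", b, "Wv")] = tWv[b];
      out[idx_name("tf", b, "Wo")] = tWo[b];
      out[idx_name("tf", b, "W1")] = tW1[b];
      out[idx_name("tf", b, "b1")] = tb1[b];
      out[idx_name("tf", b, "W2")] = tW2[b];
      out[idx_name("tf", b, "b2")] = tb2[b];
    }
    for (size_t b = 0; b < rWx.size(); ++b) {
      out[idx_name("rnn", b, "Wx")] = rWx[b];
      out[idx_name("rnn", b, "Wh")] = rWh[b];
      out[idx_name("rnn", b, "b")] = rb[b];
    }
    for (size_t b = 0; b < cW.size(); ++b) {
      out[idx_name("conv", b, "W")] = cW[b];
      out[idx_name("conv", b, "b")] = cb[b];
    }
    out["Wh"] = Wh; out["bh"] = bh;
    return out;
  }
};

static mat row_softmax(const mat& L) {
  mat M = L.each_col() - arma::max(L, 1);
  mat E = arma::exp(M);
  return E.each_col() / arma::sum(E, 1);
}

// dS given A = softmax(S) rowwise and dA
static mat softmax_backward(const mat& A, const mat& dA) {
  vec s = arma::sum(dA % A, 1);
  return A % (dA.each_col() - s);
}

// ---------------------------------------------------------------------------
// Embedding layer
// ---------------------------------------------------------------------------

struct AttnCache {           // one attention scope (a chromosome, or the panel)
  mat Em, Q, K, Vv, A;
  std::vector<int> cols;     // 0-based panel columns, scope order
  std::vector<int> st;       // allele states
  bool used = false;
};

struct EmbedCache {
  std::vector<AttnCache> scopes;   // 22 scopes (chrom-wise) or 1 (global)
  std::vector<bool> empty_chrom;
};

// groups: per chromosome, 0-based column indices (ascending position)
struct Groups {
  std::vector<std::vector<int>> cols;
  std::vector<int> chrom_of_col;   // for global pooling
  int p = 0;
  std::vector<int> all_cols;       // concatenated, chromosome order
};

static Groups parse_groups(const List& groups, int p_total) {
  Groups g;
  g.cols.resize(N_CHROM);
  g.chrom_of_col.assign(p_total, -1);
  if (groups.size() != N_CHROM) stop("expected 22 chromosome groups");
  for (int j = 0; j < N_CHROM; ++j) {
    IntegerVector cj = groups[j];
    for (int k = 0; k < cj.size(); ++k) {
      int col = cj[k] - 1;  // R is 1-based
      if (col < 0 || col >= p_total) stop("group column index out of range");
      g.cols[j].push_back(col);
      g.chrom_of_col[col] = j;
      g.all_cols.push_back(col);
    }
  }
  g.p = p_total;
  return g;
}

static void attention_forward(const Params& P, int d, AttnCache& C) {
  C.Q = C.Em * P.Wq.t();
  C.K = C.Em * P.Wk.t();
  C.Vv = C.Em * P.Wv.t();
  C.A = row_softmax(C.Q * C.K.t() / std::sqrt((double)d));
  C.used = true;
}

// backward through one attention scope: dH -> dEm (returned), accumulating
// projection-weight gradients
static mat attention_backward(const Params& P, Grads& G, int d,
                              const AttnCache& C, const mat& dH) {
  double sc = 1.0 / std::sqrt((double)d);
  mat dA = dH * C.Vv.t();
  mat dVv = C.A.t() * dH;
  mat dS = softmax_backward(C.A, dA);
  mat dQ = dS * C.K * sc;
  mat dK = dS.t() * C.Q * sc;
  G.Wq += dQ.t() * C.Em;
  G.Wk += dK.t() * C.Em;
  G.Wv += dVv.t() * C.Em;
  return dQ * P.Wq + dK * P.Wk + dVv * P.Wv;
}

// forward for one sample -> Z (22 x d); caches filled when cache != nullptr
static mat embed_forward(const int* states_row, int n_rows_stride,
                         const Groups& g, const Params& P, const Config& c,
                         EmbedCache* cache) {
  mat Z(N_CHROM, c.d, arma::fill::zeros);
  auto state_at = [&](int col) { return states_row[(size_t)col * n_rows_stride]; };

  if (c.mode == CHROM_WISE) {
    if (cache) cache->scopes.resize(N_CHROM);
    for (int j = 0; j < N_CHROM; ++j) {
      int m = (int)g.cols[j].size();
      if (m == 0) { Z.row(j) = P.null_tok.row(j); continue; }
      AttnCache local;
      AttnCache& C = cache ? cache->scopes[j] : local;
      C.Em.set_size(m, c.d);
      C.cols = g.cols[j];
      C.st.resize(m);
      for (int k = 0; k < m; ++k) {
        int col = g.cols[j][k];
        int s = state_at(col);
        C.st[k] = s;
        C.Em.row(k) = P.E.row(s) + P.P.row(col);
      }
      attention_forward(P, c.d, C);
      Z.row(j) = arma::mean(C.A * C.Vv, 0);
    }
  } else if (c.mode == GLOBAL_SNP) {
    int m = (int)g.all_cols.size();
    if (cache) cache->scopes.resize(1);
    AttnCache local;
    AttnCache& C = cache ? cache->scopes[0] : local;
    C.Em.set_size(m, c.d);
    C.cols = g.all_cols;
    C.st.resize(m);
    for (int k = 0; k < m; ++k) {
      C.st[k] = state_at(g.all_cols[k]);
      C.Em.row(k) = P.E.row(C.st[k]);
    }
    attention_forward(P, c.d, C);
    mat H = C.A * C.Vv;
    int pos = 0;
    for (int j = 0; j < N_CHROM; ++j) {
      int mj = (int)g.cols[j].size();
      if (mj == 0) { Z.row(j) = P.null_tok.row(j); continue; }
      Z.row(j) = arma::mean(H.rows(pos, pos + mj - 1), 0);
      pos += mj;
    }
  } else if (c.mode == INDEP_SNP) {
    for (int j = 0; j < N_CHROM; ++j) {
      int m = (int)g.cols[j].size();
      if (m == 0) { Z.row(j) = P.null_tok.row(j); continue; }
      rowvec acc(c.d, arma::fill::zeros);
      for (int k = 0; k < m; ++k) {
        int col = g.cols[j][k];
        acc += P.E_ind.row((arma::uword)col * c.V + state_at(col));
      }
      Z.row(j) = acc / m;
    }
  } else {  // ONE_HOT: raw one-hot padded/truncated to d, no parameters
    for (int j = 0; j < N_CHROM; ++j) {
      int m = (int)g.cols[j].size();
      if (m == 0) continue;  // zero row: no learned null token in this mode
      rowvec acc(c.d, arma::fill::zeros);
      for (int k = 0; k < m; ++k) {
        int s = state_at(g.cols[j][k]);
        if (s < c.d) acc(s) += 1.0;
      }
      Z.row(j) = acc / m;
    }
  }
  return Z;
}

static void embed_backward(const int* states_row, int n_rows_stride,
                           const Groups& g, const Params& P, const Config& c,
                           const EmbedCache& cache, const mat& dZ, Grads& G) {
  auto state_at = [&](int col) { return states_row[(size_t)col * n_rows_stride]; };
  if (c.mode == CHROM_WISE) {
    for (int j = 0; j < N_CHROM; ++j) {
      int m = (int)g.cols[j].size();
      if (m == 0) { G.null_tok.row(j) += dZ.row(j); continue; }
      const AttnCache& C = cache.scopes[j];
      mat dH = arma::repmat(dZ.row(j) / m, m, 1);
      mat dEm = attention_backward(P, G, c.d, C, dH);
      for (int k = 0; k < m; ++k) {
        G.E.row(C.st[k]) += dEm.row(k);
        G.P.row(C.cols[k]) += dEm.row(k);
      }
    }
  } else if (c.mode == GLOBAL_SNP) {
    const AttnCache& C = cache.scopes[0];
    int m = (int)C.cols.size();
    mat dH(m, c.d, arma::fill::zeros);
    int pos = 0;
    for (int j = 0; j < N_CHROM; ++j) {
      int mj = (int)g.cols[j].size();
      if (mj == 0) { G.null_tok.row(j) += dZ.row(j); continue; }
      for (int k = 0; k < mj; ++k) dH.row(pos + k) = dZ.row(j) / mj;
      pos += mj;
    }
    mat dEm = attention_backward(P, G, c.d, C, dH);
    for (int k = 0; k < m; ++k) G.E.row(C.st[k]) += dEm.row(k);
  } else if (c.mode == INDEP_SNP) {
    for (int j = 0; j < N_CHROM; ++j) {
      int m = (int)g.cols[j].size();
      if (m == 0) { G.null_tok.row(j) += dZ.row(j); continue; }
      for (int k = 0; k < m; ++k) {
        int col = g.cols[j][k];
        G.E_ind.row((arma::uword)col * c.V + state_at(col)) += dZ.row(j) / m;
      }
    }
  }
  // ONE_HOT: no parameters
}

// ---------------------------------------------------------------------------
// Backbones (input X: 22 x d tokens; output trunk row vector)
// ---------------------------------------------------------------------------

struct TfBlockCache {
  mat X, Qf, Kf, Vf, O, X2, Uraw, U;
  std::vector<mat> Ah;   // per head
};

struct BackboneCache {
  std::vector<TfBlockCache> tf;
  // recurrent: per layer, per time step
  std::vector<mat> in_seq;               // input sequence per layer (T x in)
  std::vector<std::vector<vec>> gi, gf, gg, go, cc, tc, hh;  // lstm
  std::vector<std::vector<vec>> gr, gz, gn, hterm_n;         // gru
  // conv: per layer input (T x cin) and pre-activation (T x cout)
  std::vector<mat> conv_in, conv_pre;
  mat Xfinal;
};

static rowvec backbone_forward(const mat& Z, const Params& P, const Config& c,
                               BackboneCache* cache) {
  const int T = N_CHROM;
  if (c.kind == TRANSFORMER) {
    mat X = Z;
    int dk = c.depth > 0 ? c.d / c.heads : c.d;
    double sc = 1.0 / std::sqrt((double)std::max(dk, 1));
    if (cache) cache->tf.resize(c.depth);
    for (int b = 0; b < c.depth; ++b) {
      TfBlockCache local;
      TfBlockCache& C = cache ? cache->tf[b] : local;
      C.X = X;
      C.Qf = X * P.tWq[b].t();
      C.Kf = X * P.tWk[b].t();
      C.Vf = X * P.tWv[b].t();
      C.O.set_size(T, c.d);
      C.Ah.resize(c.heads);
      for (int h = 0; h < c.heads; ++h) {
        arma::span cs(h * dk, (h + 1) * dk - 1);
        mat Ah = row_softmax(C.Qf.cols(cs) * C.Kf.cols(cs).t() * sc);
        C.Ah[h] = Ah;
        C.O.cols(cs) = Ah * C.Vf.cols(cs);
      }
      C.X2 = X + C.O * P.tWo[b].t();
      C.Uraw = C.X2 * P.tW1[b].t();
      C.Uraw.each_row() += P.tb1[b].col(0).t();
      C.U = arma::clamp(C.Uraw, 0.0, arma::datum::inf);
      X = C.X2 + C.U * P.tW2[b].t();
      X.each_row() += P.tb2[b].col(0).t();
    }
    if (cache) cache->Xfinal = X;
    return arma::mean(X, 0);
  }

  if (c.kind == LSTM || c.kind == GRU) {
    mat seq = Z;  // T x in
    if (cache) {
      cache->in_seq.resize(c.depth);
      cache->gi.assign(c.depth, {}); cache->gf.assign(c.depth, {});
      cache->gg.assign(c.depth, {}); cache->go.assign(c.depth, {});
      cache->cc.assign(c.depth, {}); cache->tc.assign(c.depth, {});
      cache->hh.assign(c.depth, {});
      cache->gr.assign(c.depth, {}); cache->gz.assign(c.depth, {});
      cache->gn.assign(c.depth, {}); cache->hterm_n.assign(c.depth, {});
    }
    rowvec trunk;
    for (int b = 0; b < c.depth; ++b) {
      if (cache) cache->in_seq[b] = seq;
      int w = c.width;
      vec h(w, arma::fill::zeros), cvec(w, arma::fill::zeros);
      mat out(T, w);
      for (int t = 0; t < T; ++t) {
        vec x = seq.row(t).t();
        if (c.kind == LSTM) {
          vec pre = P.rWx[b] * x + P.rWh[b] * h + P.rb[b].col(0);
          vec i = 1.0 / (1.0 + arma::exp(-pre.subvec(0, w - 1)));
          vec f = 1.0 / (1.0 + arma::exp(-pre.subvec(w, 2 * w - 1)));
          vec gg = arma::tanh(pre.subvec(2 * w, 3 * w - 1));
          vec o = 1.0 / (1.0 + arma::exp(-pre.subvec(3 * w, 4 * w - 1)));
          vec c_prev = cvec;
          cvec = f % c_prev + i % gg;
          vec tc = arma::tanh(cvec);
          h = o % tc;
          if (cache) {
            cache->gi[b].push_back(i); cache->gf[b].push_back(f);
            cache->gg[b].push_back(gg); cache->go[b].push_back(o);
            cache->cc[b].push_back(cvec); cache->tc[b].push_back(tc);
            cache->hh[b].push_back(h);
          }
        } else {  // GRU
          vec pre = P.rWx[b] * x + P.rb[b].col(0);
          vec ht = P.rWh[b] * h;
          vec r = 1.0 / (1.0 + arma::exp(-(pre.subvec(0, w - 1) + ht.subvec(0, w - 1))));
          vec z = 1.0 / (1.0 + arma::exp(-(pre.subvec(w, 2 * w - 1) + ht.subvec(w, 2 * w - 1))));
          vec hn = ht.subvec(2 * w, 3 * w - 1);
          vec n = arma::tanh(pre.subvec(2 * w, 3 * w - 1) + r % hn);
          h = (1.0 - z) % n + z % h;
          if (cache) {
            cache->gr[b].push_back(r); cache->gz[b].push_back(z);
            cache->gn[b].push_back(n); cache->hterm_n[b].push_back(hn);
            cache->hh[b].push_back(h);
          }
        }
        out.row(t) = h.t();
      }
      seq = out;
      trunk = h.t();
    }
    return trunk;
  }

  // CNN / TCN: 1-D convolutions along the token axis, kernel 3
  mat X = Z;
  if (cache) { cache->conv_in.resize(c.depth); cache->conv_pre.resize(c.depth); }
  for (int b = 0; b < c.depth; ++b) {
    int cin = X.n_cols, cout = c.width;
    const mat& W = P.cW[b];   // cout x 3*cin, taps [-1, 0, +1] or [0,-dil,-2dil]
    mat pre(T, cout);
    pre.each_row() = P.cb[b].col(0).t();
    if (c.kind == CNN) {
      for (int tau = -1; tau <= 1; ++tau) {
        mat Wt = W.cols((tau + 1) * cin, (tau + 2) * cin - 1);
        for (int t = 0; t < T; ++t) {
          int src = t + tau;
          if (src < 0 || src >= T) continue;
          pre.row(t) += X.row(src) * Wt.t();
        }
      }
    } else {  // TCN: causal, dilated
      int dil = 1 << b;
      for (int tau = 0; tau <= 2; ++tau) {
        mat Wt = W.cols(tau * cin, (tau + 1) * cin - 1);
        for (int t = 0; t < T; ++t) {
          int src = t - tau * dil;
          if (src < 0) continue;
          pre.row(t) += X.row(src) * Wt.t();
        }
      }
    }
    if (cache) { cache->conv_in[b] = X; cache->conv_pre[b] = pre; }
    X = arma::clamp(pre, 0.0, arma::datum::inf);
  }
  if (cache) cache->Xfinal = X;
  return arma::mean(X, 0);
}

static mat backbone_backward(const Params& P, const Config& c,
                             const BackboneCache& cache, const rowvec& dtrunk,
                             Grads& G) {
  const int T = N_CHROM;
  if (c.kind == TRANSFORMER) {
    mat dX = arma::repmat(dtrunk / T, T, 1);
    int dk = c.depth > 0 ? c.d / c.heads : c.d;
    double sc = 1.0 / std::sqrt((double)std::max(dk, 1));
    for (int b = c.depth - 1; b >= 0; --b) {
      const TfBlockCache& C = cache.tf[b];
      // X3 = X2 + U W2^T + b2
      G.tb2[b].col(0) += arma::sum(dX, 0).t();
      mat dU = dX * P.tW2[b];
      G.tW2[b] += dX.t() * C.U;
      mat dUraw = dU % arma::conv_to<mat>::from(C.Uraw > 0);
      G.tb1[b].col(0) += arma::sum(dUraw, 0).t();
      mat dX2 = dX + dUraw * P.tW1[b];
      G.tW1[b] += dUraw.t() * C.X2;
      // X2 = X + O Wo^T
      mat dO = dX2 * P.tWo[b];
      G.tWo[b] += dX2.t() * C.O;
      mat dQf(T, c.d, arma::fill::zeros), dKf(T, c.d, arma::fill::zeros),
          dVf(T, c.d, arma::fill::zeros);
      for (int h = 0; h < c.heads; ++h) {
        arma::span cs(h * dk, (h + 1) * dk - 1);
        const mat& Ah = C.Ah[h];
        mat dOh = dO.cols(cs);
        mat dAh = dOh * C.Vf.cols(cs).t();
        dVf.cols(cs) = Ah.t() * dOh;
        mat dSh = softmax_backward(Ah, dAh);
        dQf.cols(cs) = dSh * C.Kf.cols(cs) * sc;
        dKf.cols(cs) = dSh.t() * C.Qf.cols(cs) * sc;
      }
      G.tWq[b] += dQf.t() * C.X;
      G.tWk[b] += dKf.t() * C.X;
      G.tWv[b] += dVf.t() * C.X;
      dX = dX2 + dQf * P.tWq[b] + dKf * P.tWk[b] + dVf * P.tWv[b];
    }
    return dX;
  }

  if (c.kind == LSTM || c.kind == GRU) {
    int w = c.width;
    // upstream gradient on each layer's output sequence
    mat dseq(T, w, arma::fill::zeros);
    dseq.row(T - 1) = dtrunk;
    for (int b = c.depth - 1; b >= 0; --b) {
      const mat& in = cache.in_seq[b];
      int din = in.n_cols;
      mat dprev(T, din, arma::fill::zeros);
      vec dh(w, arma::fill::zeros), dc(w, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        dh += dseq.row(t).t();
        vec x = in.row(t).t();
        vec h_prev = (t > 0) ? cache.hh[b][t - 1] : vec(w, arma::fill::zeros);
        if (c.kind == LSTM) {
          const vec &i = cache.gi[b][t], &f = cache.gf[b][t],
                    &gg = cache.gg[b][t], &o = cache.go[b][t],
                    &tc = cache.tc[b][t];
          vec c_prev = (t > 0) ? cache.cc[b][t - 1] : vec(w, arma::fill::zeros);
          vec do_ = dh % tc;
          dc += dh % o % (1.0 - tc % tc);
          vec di = dc % gg, df = dc % c_prev, dg = dc % i;
          vec dpre(4 * w);
          dpre.subvec(0, w - 1) = di % i % (1.0 - i);
          dpre.subvec(w, 2 * w - 1) = df % f % (1.0 - f);
          dpre.subvec(2 * w, 3 * w - 1) = dg % (1.0 - gg % gg);
          dpre.subvec(3 * w, 4 * w - 1) = do_ % o % (1.0 - o);
          G.rWx[b] += dpre * x.t();
          G.rWh[b] += dpre * h_prev.t();
          G.rb[b].col(0) += dpre;
          dprev.row(t) += (P.rWx[b].t() * dpre).t();
          dh = P.rWh[b].t() * dpre;
          dc = dc % f;
        } else {  // GRU
          const vec &r = cache.gr[b][t], &z = cache.gz[b][t],
                    &n = cache.gn[b][t], &hn = cache.hterm_n[b][t];
          vec dn = dh % (1.0 - z);
          vec dz = dh % (h_prev - n);
          vec dh_prev = dh % z;
          vec dpre_n = dn % (1.0 - n % n);
          vec dr = dpre_n % hn;
          vec dhterm_n = dpre_n % r;
          vec dpre_r = dr % r % (1.0 - r);
          vec dpre_z = dz % z % (1.0 - z);
          vec dpre(3 * w), dhterm(3 * w);
          dpre.subvec(0, w - 1) = dpre_r;
          dpre.subvec(w, 2 * w - 1) = dpre_z;
          dpre.subvec(2 * w, 3 * w - 1) = dpre_n;
          dhterm.subvec(0, w - 1) = dpre_r;
          dhterm.subvec(w, 2 * w - 1) = dpre_z;
          dhterm.subvec(2 * w, 3 * w - 1) = dhterm_n;
          G.rWx[b] += dpre * x.t();
          G.rWh[b] += dhterm * h_prev.t();
          G.rb[b].col(0) += dpre;
          dprev.row(t) += (P.rWx[b].t() * dpre).t();
          dh = dh_prev + P.rWh[b].t() * dhterm;
        }
      }
      dseq = dprev;  // becomes upstream for the layer below
      if (b > 0 && (int)dprev.n_cols != w)
        stop("internal: stacked recurrent width mismatch");
    }
    return dseq;  // gradient on Z
  }

  // CNN / TCN
  mat dX = arma::repmat(dtrunk / T, T, 1);
  for (int b = c.depth - 1; b >= 0; --b) {
    const mat& in = cache.conv_in[b];
    const mat& pre = cache.conv_pre[b];
    int cin = in.n_cols;
    mat dpre = dX % arma::conv_to<mat>::from(pre > 0);
    G.cb[b].col(0) += arma::sum(dpre, 0).t();
    mat dprev(T, cin, arma::fill::zeros);
    if (c.kind == CNN) {
      for (int tau = -1; tau <= 1; ++tau) {
        int off = (tau + 1) * cin;
        mat Wt = P.cW[b].cols(off, off + cin - 1);
        for (int t = 0; t < T; ++t) {
          int src = t + tau;
          if (src < 0 || src >= T) continue;
          G.cW[b].cols(off, off + cin - 1) += dpre.row(t).t() * in.row(src);
          dprev.row(src) += dpre.row(t) * Wt;
        }
      }
    } else {
      int dil = 1 << b;
      for (int tau = 0; tau <= 2; ++tau) {
        int off = tau * cin;
        mat Wt = P.cW[b].cols(off, off + cin - 1);
        for (int t = 0; t < T; ++t) {
          int src = t - tau * dil;
          if (src < 0) continue;
          G.cW[b].cols(off, off + cin - 1) += dpre.row(t).t() * in.row(src);
          dprev.row(src) += dpre.row(t) * Wt;
        }
      }
    }
    dX = dprev;
  }
  return dX;
}

// stable binary cross-entropy from the logit
static double bce_from_logit(double z, double y) {
  return std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::abs(z)));
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_loss_grad(IntegerMatrix states, List groups, List params, List config,
                   NumericMatrix labels, NumericVector task_weights) {
  Config c = parse_config(config);
  Params P = load_params(params, c);
  Groups g = parse_groups(groups, states.ncol());
  int n = states.nrow();
  if (labels.nrow() != n || labels.ncol() != 6) stop("labels must be n x 6");
  if (task_weights.size() != 6) stop("task_weights must have length 6");

  Grads G;
  G.init_like(P, c);
  double loss = 0.0;
  NumericMatrix logits_out(n, 6);
  const int* sp = INTEGER(states);

  for (int i = 0; i < n; ++i) {
    EmbedCache ec;
    BackboneCache bc;
    mat Z = embed_forward(sp + i, n, g, P, c, &ec);
    rowvec trunk = backbone_forward(Z, P, c, &bc);
    rowvec logit = trunk * P.Wh.t() + P.bh.col(0).t();
    rowvec dlogit(6);
    for (int dI = 0; dI < 6; ++dI) {
      double z = logit(dI), y = labels(i, dI);
      logits_out(i, dI) = z;
      loss += task_weights[dI] * bce_from_logit(z, y) / n;
      double p = 1.0 / (1.0 + std::exp(-z));
      dlogit(dI) = task_weights[dI] * (p - y) / n;
    }
    G.Wh += dlogit.t() * trunk;
    G.bh.col(0) += dlogit.t();
    rowvec dtrunk = dlogit * P.Wh;
    mat dZ = backbone_backward(P, c, bc, dtrunk, G);
    embed_backward(sp + i, n, g, P, c, ec, dZ, G);
  }

  return List::create(_["loss"] = loss, _["grads"] = G.to_list(c),
                      _["logits"] = logits_out);
}

// [[Rcpp::export]]
List cpp_predict(IntegerMatrix states, List groups, List params, List config,
                 bool return_Z = false, bool return_attention = false) {
  Config c = parse_config(config);
  Params P = load_params(params, c);
  Groups g = parse_groups(groups, states.ncol());
  int n = states.nrow();
  NumericMatrix logits(n, 6), probs(n, 6);
  const int* sp = INTEGER(states);
  int p_total = states.ncol();
  vec attn_raw(p_total, arma::fill::zeros);
  vec attn_val(p_total, arma::fill::zeros);
  bool attn_ok = (c.mode == CHROM_WISE || c.mode == GLOBAL_SNP);
  NumericVector Zout;
  if (return_Z) { Zout = NumericVector(Dimension(n, N_CHROM, c.d)); }

  for (int i = 0; i < n; ++i) {
    EmbedCache ec;
    mat Z = embed_forward(sp + i, n, g, P, c,
                          (return_attention && attn_ok) ? &ec : nullptr);
    rowvec trunk = backbone_forward(Z, P, c, nullptr);
    rowvec logit = trunk * P.Wh.t() + P.bh.col(0).t();
    for (int dI = 0; dI < 6; ++dI) {
      logits(i, dI) = logit(dI);
      probs(i, dI) = 1.0 / (1.0 + std::exp(-logit(dI)));
    }
    if (return_Z) {
      for (int j = 0; j < N_CHROM; ++j)
        for (int k = 0; k < c.d; ++k)
          Zout[i + (size_t)n * j + (size_t)n * N_CHROM * k] = Z(j, k);
    }
    if (return_attention && attn_ok) {
      for (const AttnCache& C : ec.scopes) {
        if (!C.used) continue;
        vec incoming = arma::sum(C.A, 0).t();          // mass received by SNP l
        for (size_t k = 0; k < C.cols.size(); ++k) {
          attn_raw(C.cols[k]) += incoming(k) / n;
          attn_val(C.cols[k]) += incoming(k) * arma::norm(C.Vv.row(k), 2) / n;
        }
      }
    }
  }

  List out = List::create(_["logits"] = logits, _["probs"] = probs);
  if (return_Z) out["Z"] = Zout;
  if (return_attention && attn_ok) {
    out["attn_raw"] = NumericVector(attn_raw.begin(), attn_raw.end());
    out["attn_value"] = NumericVector(attn_val.begin(), attn_val.end());
  }
  return out;
}

// single-representation backbone pass (contract-level op)
// [[Rcpp::export]]
NumericVector cpp_backbone_forward(NumericMatrix Z, List params, List config) {
  Config c = parse_config(config);
  Params P = load_params(params, c);
  mat Zm = as<mat>(Z);
  if ((int)Zm.n_rows != N_CHROM) stop("Z must have 22 rows");
  rowvec trunk = backbone_forward(Zm, P, c, nullptr);
  return NumericVector(trunk.begin(), trunk.end());
}
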