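// Transformer encoder with Shaw-style relative position embeddings (RPE),
// pre-layer normalization, mean pooling, and source (multi-task) or target
// (single-output) heads. Forward pass plus hand-derived backpropagation;
// gradients are verified against finite differences in the test suite.
//
// Conventions:
//  - tokens: L x B integer matrix, 1-based ids into the embedding table
//  - rclass: L x L integer matrix, 1-based RPE class index for (i, j)
//  - params: named R list of numeric matrices (vectors as n x 1)
//  - loss:   sum over tasks of the per-task batch MSE

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

struct LNCache {
  mat xhat;
  vec invstd;
};

static mat ln_fwd(const mat& x, const vec& g, const vec& b, LNCache& c) {
  const arma::uword L = x.n_rows, d = x.n_cols;
  c.xhat.set_size(L, d);
  c.invstd.set_size(L);
  mat out(L, d);
  for (arma::uword i = 0; i < L; ++i) {
    const rowvec r = x.row(i);
    const double mu = arma::mean(r);
    const rowvec cen = r - mu;
    const double var = arma::mean(cen % cen);
    const double inv = 1.0 / std::sqrt(var + LN_EPS);
    c.invstd(i) = inv;
    c.xhat.row(i) = cen * inv;
    out.row(i) = c.xhat.row(i) % g.t() + b.t();
  }
  return out;
}

static mat ln_bwd(const mat& dy, const vec& g, const LNCache& c,
                  mat& dg, mat& db) {
  const arma::uword L = dy.n_rows, d = dy.n_cols;
  mat dx(L, d);
  for (arma::uword i = 0; i < L; ++i) {
    const rowvec dxhat = dy.row(i) % g.t();
    const double m1 = arma::mean(dxhat);
    const double m2 = arma::mean(dxhat % c.xhat.row(i));
    dx.row(i) = c.invstd(i) * (dxhat - m1 - c.xhat.row(i) * m2);
    dg += (dy.row(i) % c.xhat.row(i)).t();
    db += dy.row(i).t();
  }
  return dx;
}

static mat softmax_rows(const mat& e) {
  mat out(e.n_rows, e.n_cols);
  for (arma::uword i = 0; i < e.n_rows; ++i) {
    rowvec r = e.row(i) - e.row(i).max();
    r = arma::exp(r);
    out.row(i) = r / arma::accu(r);
  }
  return out;
}

// dropout mask with inverted scaling, drawn from the R RNG; empty matrix
// means "no dropout"
static mat drop_mask(arma::uword r, arma::uword c, double rate) {
  mat m(r, c);
  const double keep = 1.0 - rate;
  for (arma::uword j = 0; j < c; ++j)
    for (arma::uword i = 0; i < r; ++i)
      m(i, j) = unif_rand() < keep ? 1.0 / keep : 0.0;
  return m;
}

static inline mat apply_mask(const mat& x, const mat& m) {
  return m.n_elem ? mat(x % m) : x;
}

struct HeadCache {
  mat alpha;       // pre-dropout attention, L x L
  mat mask;        // attention dropout mask (may be empty)
  mat alpha_d;     // post-dropout attention
  mat Wa;          // class-gathered attention weights, L x C
};

struct LayerCache {
  LNCache ln1, ln2;
  mat A1, Q, K, V;
  std::vector<HeadCache> heads;
  mat O, AO, m_attn_out;
  mat X1;
  mat A2, Z1, H1d, m_ffh, m_ff2;
  mat X2;
};

struct SeqCache {
  mat X0;
  std::vector<LayerCache> layers;
  LNCache lnf;
  mat Xf;
  rowvec pooled;
  rowvec z_fc, fc;       // pre/post ReLU of the pooled hidden layer
  rowvec feat, feat_mask;  // target-head feature and its dropout mask
  rowvec pred;
};

struct Config {
  int d, n_layers, n_heads, ff, head_hidden, n_tasks, n_classes;
  int dh;
  double dropout, head_dropout;
  bool target;     // single-output head
  bool attach_fc;  // target head attaches after the fc layer
};

static Config read_cfg(const List& cfg) {
  Config c;
  c.d = as<int>(cfg["embed_dim"]);
  c.n_layers = as<int>(cfg["n_layers"]);
  c.n_heads = as<int>(cfg["n_heads"]);
  c.ff = as<int>(cfg["ff_dim"]);
  c.head_hidden = as<int>(cfg["head_hidden"]);
  c.n_tasks = as<int>(cfg["n_tasks"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.head_dropout = as<double>(cfg["head_dropout"]);
  std::string ht = as<std::string>(cfg["head_type"]);
  c.target = (ht == "target");
  std::string at = as<std::string>(cfg["head_attach"]);
  c.attach_fc = (at == "fc");
  c.dh = c.d / c.n_heads;
  return c;
}

struct ParamSet {
  mat embed;
  std::vector<mat> ln1_g, ln1_b, ln2_g, ln2_b;
  std::vector<mat> wq, bq, wk, bk, wv, bv, wo, bo;
  std::vector<mat> rk, rv;
  std::vector<mat> w1, b1, w2, b2;
  mat fln_g, fln_b;
  mat fc_w, fc_b;
  mat out_w, out_b;    // source head
  mat head_w, head_b;  // target head
};

static std::string lname(int l, const char* nm) {
  return "l" + std::to_string(l) + "_" + nm;
}

static ParamSet read_params(const List& p, const Config& c) {
  ParamSet ps;
  ps.embed = as<mat>(p["embed"]);
  for (int l = 0; l < c.n_layers; ++l) {
    ps.ln1_g.push_back(as<mat>(p[lname(l, "ln1_g")]));
    ps.ln1_b.push_back(as<mat>(p[lname(l, "ln1_b")]));
    ps.wq.push_back(as<mat>(p[lname(l, "wq")]));
    ps.bq.push_back(as<mat>(p[lname(l, "bq")]));
    ps.wk.push_back(as<mat>(p[lname(l, "wk")]));
    ps.bk.push_back(as<mat>(p[lname(l, "bk")]));
    ps.wv.push_back(as<mat>(p[lname(l, "wv")]));
    ps.bv.push_back(as<mat>(p[lname(l, "bv")]));
    ps.wo.push_back(as<mat>(p[lname(l, "wo")]));
    ps.bo.push_back(as<mat>(p[lname(l, "bo")]));
    ps.rk.push_back(as<mat>(p[lname(l, "rk")]));
    ps.rv.push_back(as<mat>(p[lname(l, "rv")]));
    ps.ln2_g.push_back(as<mat>(p[lname(l, "ln2_g")]));
    ps.ln2_b.push_back(as<mat>(p[lname(l, "ln2_b")]));
    ps.w1.push_back(as<mat>(p[lname(l, "w1")]));
    ps.b1.push_back(as<mat>(p[lname(l, "b1")]));
    ps.w2.push_back(as<mat>(p[lname(l, "w2")]));
    ps.b2.push_back(as<mat>(p[lname(l, "b2")]));
  }
  ps.fln_g = as<mat>(p["final_ln_g"]);
  ps.fln_b = as<mat>(p["final_ln_b"]);
  if (!c.target || c.attach_fc) {
    ps.fc_w = as<mat>(p["fc_w"]);
    ps.fc_b = as<mat>(p["fc_b"]);
  }
  if (c.target) {
    ps.head_w = as<mat>(p["head_w"]);
    ps.head_b = as<mat>(p["head_b"]);
  } else {
    ps.out_w = as<mat>(p["out_w"]);
    ps.out_b = as<mat>(p["out_b"]);
  }
  return ps;
}

// gradients mirrored onto the parameter layout
struct GradSet {
  std::map<std::string, mat> g;
  void init(const std::string& nm, arma::uword r, arma::uword c) {
    g[nm] = mat(r, c, arma::fill::zeros);
  }
  mat& at(const std::string& nm) { return g.find(nm)->second; }
};

// forward for one sequence; fills the cache
static void forward_seq(const arma::ivec& tok, const arma::imat& rc,
                        const ParamSet& ps, const Config& c, bool training,
                        SeqCache& sc, mat* attn_accum) {
  const arma::uword L = tok.n_elem;
  sc.X0.set_size(L, c.d);
  for (arma::uword i = 0; i < L; ++i)
    sc.X0.row(i) = ps.embed.row(tok(i) - 1);
  mat X = sc.X0;
  sc.layers.resize(c.n_layers);
  const double srt = std::sqrt((double)c.dh);
  for (int l = 0; l < c.n_layers; ++l) {
    LayerCache& lc = sc.layers[l];
    lc.A1 = ln_fwd(X, ps.ln1_g[l].col(0), ps.ln1_b[l].col(0), lc.ln1);
    lc.Q = lc.A1 * ps.wq[l];
    lc.Q.each_row() += ps.bq[l].col(0).t();
    lc.K = lc.A1 * ps.wk[l];
    lc.K.each_row() += ps.bk[l].col(0).t();
    lc.V = lc.A1 * ps.wv[l];
    lc.V.each_row() += ps.bv[l].col(0).t();
    lc.heads.resize(c.n_heads);
    lc.O.set_size(L, c.d);
    for (int h = 0; h < c.n_heads; ++h) {
      HeadCache& hc = lc.heads[h];
      const arma::uword c0 = h * c.dh, c1 = (h + 1) * c.dh - 1;
      const mat Qh = lc.Q.cols(c0, c1);
      const mat Kh = lc.K.cols(c0, c1);
      const mat Vh = lc.V.cols(c0, c1);
      mat E = Qh * Kh.t();
      const mat P = Qh * ps.rk[l].t();  // L x C
      for (arma::uword i = 0; i < L; ++i)
        for (arma::uword j = 0; j < L; ++j)
          E(i, j) += P(i, rc(i, j) - 1);
      E /= srt;
      hc.alpha = softmax_rows(E);
      if (attn_accum) *attn_accum += hc.alpha;
      if (training && c.dropout > 0) {
        hc.mask = drop_mask(L, L, c.dropout);
        hc.alpha_d = hc.alpha % hc.mask;
      } else {
        hc.alpha_d = hc.alpha;
      }
      hc.Wa.zeros(L, c.n_classes);
      for (arma::uword i = 0; i < L; ++i)
        for (arma::uword j = 0; j < L; ++j)
          hc.Wa(i, rc(i, j) - 1) += hc.alpha_d(i, j);
      lc.O.cols(c0, c1) = hc.alpha_d * Vh + hc.Wa * ps.rv[l];
    }
    lc.AO = lc.O * ps.wo[l];
    lc.AO.each_row() += ps.bo[l].col(0).t();
    if (training && c.dropout > 0)
      lc.m_attn_out = drop_mask(L, c.d, c.dropout);
    lc.X1 = X + apply_mask(lc.AO, lc.m_attn_out);
    lc.A2 = ln_fwd(lc.X1, ps.ln2_g[l].col(0), ps.ln2_b[l].col(0), lc.ln2);
    lc.Z1 = lc.A2 * ps.w1[l];
    lc.Z1.each_row() += ps.b1[l].col(0).t();
    mat H1 = arma::clamp(lc.Z1, 0.0, arma::datum::inf);
    if (training && c.dropout > 0) {
      lc.m_ffh = drop_mask(L, c.ff, c.dropout);
      lc.H1d = H1 % lc.m_ffh;
    } else {
      lc.H1d = H1;
    }
    mat Z2 = lc.H1d * ps.w2[l];
    Z2.each_row() += ps.b2[l].col(0).t();
    if (training && c.dropout > 0)
      lc.m_ff2 = drop_mask(L, c.d, c.dropout);
    lc.X2 = lc.X1 + apply_mask(Z2, lc.m_ff2);
    X = lc.X2;
  }
  sc.Xf = ln_fwd(X, ps.fln_g.col(0), ps.fln_b.col(0), sc.lnf);
  sc.pooled = arma::mean(sc.Xf, 0);
  const bool use_fc = !c.target || c.attach_fc;
  if (use_fc) {
    sc.z_fc = sc.pooled * ps.fc_w + ps.fc_b.col(0).t();
    sc.fc = arma::clamp(sc.z_fc, 0.0, arma::datum::inf);
  }
  if (c.target) {
    sc.feat = c.attach_fc ? sc.fc : sc.pooled;
    rowvec fd = sc.feat;
    if (training && c.head_dropout > 0) {
      sc.feat_mask = drop_mask(1, sc.feat.n_elem, c.head_dropout);
      fd = sc.feat % sc.feat_mask;
    }
    sc.pred = fd * ps.head_w + ps.head_b(0, 0);
  } else {
    sc.pred = sc.fc * ps.out_w + ps.out_b.col(0).t();
  }
}

// backward for one sequence; accumulates into gs
static void backward_seq(const arma::ivec& tok, const arma::imat& rc,
                         const ParamSet& ps, const Config& c,
                         const SeqCache& sc, const rowvec& dpred,
                         bool training, GradSet& gs) {
  const arma::uword L = tok.n_elem;
  const double srt = std::sqrt((double)c.dh);
  rowvec dpooled(c.d, arma::fill::zeros);
  const bool use_fc = !c.target || c.attach_fc;
  rowvec dfc;
  if (c.target) {
    rowvec fd = sc.feat;
    if (training && sc.feat_mask.n_elem) fd = sc.feat % sc.feat_mask;
    gs.at("head_w") += fd.t() * dpred;
    gs.at("head_b")(0, 0) += dpred(0);
    rowvec dfeat = dpred(0) * ps.head_w.col(0).t();
    if (training && sc.feat_mask.n_elem) dfeat = dfeat % sc.feat_mask;
    if (c.attach_fc) dfc = dfeat; else dpooled = dfeat;
  } else {
    gs.at("out_w") += sc.fc.t() * dpred;
    gs.at("out_b") += dpred.t();
    dfc = dpred * ps.out_w.t();
  }
  if (use_fc && dfc.n_elem) {
    rowvec dz = dfc;
    for (arma::uword k = 0; k < dz.n_elem; ++k)
      if (sc.z_fc(k) <= 0) dz(k) = 0;
    gs.at("fc_w") += sc.pooled.t() * dz;
    gs.at("fc_b") += dz.t();
    dpooled += dz * ps.fc_w.t();
  }
  mat dXf(L, c.d);
  for (arma::uword i = 0; i < L; ++i) dXf.row(i) = dpooled / (double)L;
  mat dX = ln_bwd(dXf, ps.fln_g.col(0), sc.lnf, gs.at("final_ln_g"),
                  gs.at("final_ln_b"));
  for (int l = c.n_layers - 1; l >= 0; --l) {
    const LayerCache& lc = sc.layers[l];
    // feed-forward sublayer
    mat dZ2 = apply_mask(dX, lc.m_ff2);
    gs.at(lname(l, "w2")) += lc.H1d.t() * dZ2;
    gs.at(lname(l, "b2")) += arma::sum(dZ2, 0).t();
    mat dH1 = dZ2 * ps.w2[l].t();
    if (lc.m_ffh.n_elem) dH1 %= lc.m_ffh;
    mat dZ1 = dH1;
    dZ1.elem(arma::find(lc.Z1 <= 0)).zeros();
    gs.at(lname(l, "w1")) += lc.A2.t() * dZ1;
    gs.at(lname(l, "b1")) += arma::sum(dZ1, 0).t();
    mat dA2 = dZ1 * ps.w1[l].t();
    mat dX1 = dX + ln_bwd(dA2, ps.ln2_g[l].col(0), lc.ln2,
                          gs.at(lname(l, "ln2_g")),
                          gs.at(lname(l, "ln2_b")));
    // attention sublayer
    mat dAO = apply_mask(dX1, lc.m_attn_out);
    gs.at(lname(l, "wo")) += lc.O.t() * dAO;
    gs.at(lname(l, "bo")) += arma::sum(dAO, 0).t();
    mat dO = dAO * ps.wo[l].t();
    mat dQ(L, c.d, arma::fill::zeros), dK(L, c.d, arma::fill::zeros),
        dV(L, c.d, arma::fill::zeros);
    for (int h = 0; h < c.n_heads; ++h) {
      const HeadCache& hc = lc.heads[h];
      const arma::uword c0 = h * c.dh, c1 = (h + 1) * c.dh - 1;
      const mat Qh = lc.Q.cols(c0, c1);
      const mat Kh = lc.K.cols(c0, c1);
      const mat Vh = lc.V.cols(c0, c1);
      const mat dOh = dO.cols(c0, c1);
      mat dalpha_d = dOh * Vh.t();
      const mat Gm = dOh * ps.rv[l].t();  // L x C
      for (arma::uword i = 0; i < L; ++i)
        for (arma::uword j = 0; j < L; ++j)
          dalpha_d(i, j) += Gm(i, rc(i, j) - 1);
      dV.cols(c0, c1) = hc.alpha_d.t() * dOh;
      gs.at(lname(l, "rv")) += hc.Wa.t() * dOh;
      mat dalpha = hc.mask.n_elem ? mat(dalpha_d % hc.mask) : dalpha_d;
      mat dE(L, L);
      for (arma::uword i = 0; i < L; ++i) {
        const rowvec a = hc.alpha.row(i);
        const rowvec da = dalpha.row(i);
        dE.row(i) = a % (da - arma::accu(da % a));
      }
      dE /= srt;
      mat Wd(L, c.n_classes, arma::fill::zeros);
      for (arma::uword i = 0; i < L; ++i)
        for (arma::uword j = 0; j < L; ++j)
          Wd(i, rc(i, j) - 1) += dE(i, j);
      dQ.cols(c0, c1) = dE * Kh + Wd * ps.rk[l];
      dK.cols(c0, c1) = dE.t() * Qh;
      gs.at(lname(l, "rk")) += Wd.t() * Qh;
    }
    gs.at(lname(l, "wq")) += lc.A1.t() * dQ;
    gs.at(lname(l, "bq")) += arma::sum(dQ, 0).t();
    gs.at(lname(l, "wk")) += lc.A1.t() * dK;
    gs.at(lname(l, "bk")) += arma::sum(dK, 0).t();
    gs.at(lname(l, "wv")) += lc.A1.t() * dV;
    gs.at(lname(l, "bv")) += arma::sum(dV, 0).t();
    mat dA1 = dQ * ps.wq[l].t() + dK * ps.wk[l].t() + dV * ps.wv[l].t();
    dX = dX1 + ln_bwd(dA1, ps.ln1_g[l].col(0), lc.ln1,
                      gs.at(lname(l, "ln1_g")), gs.at(lname(l, "ln1_b")));
  }
  mat& ge = gs.at("embed");
  for (arma::uword i = 0; i < L; ++i)
    ge.row(tok(i) - 1) += dX.row(i);
}

// [[Rcpp::export]]
List nn_run_cpp(IntegerMatrix tokens_, IntegerMatrix rclass_, List params,
                List cfg_, SEXP targets_, bool training, int dropout_seed,
                bool want_grads, bool want_attn, bool want_features,
                bool want_encodings) {
  const Config c = read_cfg(cfg_);
  const ParamSet ps = read_params(params, c);
  const arma::imat tokens = as<arma::imat>(tokens_);
  const arma::imat rc = as<arma::imat>(rclass_);
  const arma::uword L = tokens.n_rows, B = tokens.n_cols;
  if (rc.n_rows != L || rc.n_cols != L)
    stop("relative-distance map does not match sequence length");
  const int n_out = c.target ? 1 : c.n_tasks;

  bool have_targets = !Rf_isNull(targets_);
  mat targets;
  if (have_targets) {
    targets = as<mat>(targets_);
    if (targets.n_rows != B || targets.n_cols != (arma::uword)n_out)
      stop("targets must be batch x n_outputs");
  }
  if (want_grads && !have_targets)
    stop("gradients require targets");
  (void)dropout_seed;  // masks come from the R RNG, seeded caller-side

  mat attn_accum;
  if (want_attn) attn_accum.zeros(L, L);

  std::vector<SeqCache> caches(B);
  mat pred(B, n_out);
  mat feat_fc, feat_pooled;
  arma::cube enc;
  const bool use_fc = !c.target || c.attach_fc;
  if (want_features) {
    if (use_fc) feat_fc.set_size(B, c.head_hidden);
    feat_pooled.set_size(B, c.d);
  }
  if (want_encodings) enc.set_size(L, c.d, B);
  for (arma::uword b = 0; b < B; ++b) {
    arma::ivec tok = tokens.col(b);
    forward_seq(tok, rc, ps, c, training, caches[b],
                want_attn ? &attn_accum : nullptr);
    pred.row(b) = caches[b].pred;
    if (want_features) {
      if (use_fc) feat_fc.row(b) = caches[b].fc;
      feat_pooled.row(b) = caches[b].pooled;
    }
    if (want_encodings) enc.slice(b) = caches[b].Xf;
  }

  double loss = NA_REAL;
  List grads_out = R_NilValue;
  if (have_targets) {
    const mat err = pred - targets;
    loss = arma::accu(arma::mean(err % err, 0));
    if (want_grads) {
      GradSet gs;
      CharacterVector nms = params.names();
      for (int k = 0; k < nms.size(); ++k) {
        std::string nm = as<std::string>(nms[k]);
        // only parameters on the active computation path get gradients
        if (c.target && (nm == "out_w" || nm == "out_b")) continue;
        if (c.target && !c.attach_fc && (nm == "fc_w" || nm == "fc_b"))
          continue;
        if (!c.target && (nm == "head_w" || nm == "head_b")) continue;
        mat m = as<mat>(params[nm]);
        gs.init(nm, m.n_rows, m.n_cols);
      }
      const mat dpred = 2.0 * err / (double)B;
      for (arma::uword b = 0; b < B; ++b)
        backward_seq(tokens.col(b), rc, ps, c, caches[b], dpred.row(b),
                     training, gs);
      List gl;
      for (auto& kv : gs.g) gl[kv.first] = wrap(kv.second);
      grads_out = gl;
    }
  }

  List out = List::create(_["pred"] = wrap(pred), _["loss"] = loss,
                          _["grads"] = grads_out);
  if (want_attn)
    out["attn"] = wrap(mat(attn_accum /
                           (double)(c.n_layers * c.n_heads * B)));
  if (want_features) {
    out["feat_pooled"] = wrap(feat_pooled);
    if (use_fc) out["feat_fc"] = wrap(feat_fc);
  }
  if (want_encodings) out["encodings"] = wrap(enc);
  return out;
}
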