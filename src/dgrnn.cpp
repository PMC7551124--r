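// Core numerics for the knowledge-graph-attention LSTM:
// sinusoidal time encoding, forward pass (full / nk / np variants),
// exact reverse-mode gradients, and the Adam training loop.
//
// Orientation conventions:
//   entity/relation embeddings arrive as (n x d) from R and are kept
//   transposed (d x n) internally so columns are vectors;
//   LSTM gate order in the packed weight matrices is [i; f; o; c].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static const int V_FULL = 0, V_NK = 1, V_NP = 2;

// ---------------------------------------------------------------------------
// time encoding

static mat time_encode_mat(const vec& times, int tdim) {
  const uword T = times.n_elem;
  mat P(T, tdim);
  for (int k = 0; k < tdim / 2; ++k) {
    const double freq = std::pow(10000.0, -(2.0 * k) / tdim);
    for (uword t = 0; t < T; ++t) {
      P(t, 2 * k)     = std::sin(times[t] * freq);
      P(t, 2 * k + 1) = std::cos(times[t] * freq);
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_time_encoding(NumericVector times, int time_dim) {
  vec tv(times.begin(), times.size());
  return wrap(time_encode_mat(tv, time_dim));
}

// ---------------------------------------------------------------------------
// parameter container

struct Params {
  mat E;    // d x n_ent   (entity/code embeddings, transposed from R)
  mat R;    // d x n_rel
  mat Wx;   // 4H x D      (D = d + time_dim)
  mat Wh;   // 4H x H
  vec b;    // 4H
  mat Wa;   // A x (H + 3d)
  vec ba;   // A
  vec ua;   // A
  vec Wo;   // H
  double bo;
  vec gnull; // d
  int d, H, A, tdim;
};

static Params unpack_params(const List& p) {
  Params q;
  q.E  = arma::trans(as<mat>(p["emb_entity"]));
  q.R  = arma::trans(as<mat>(p["emb_relation"]));
  q.Wx = as<mat>(p["Wx"]);
  q.Wh = as<mat>(p["Wh"]);
  q.b  = as<vec>(p["b"]);
  q.Wa = as<mat>(p["Wa"]);
  q.ba = as<vec>(p["ba"]);
  q.ua = as<vec>(p["ua"]);
  q.Wo = as<vec>(p["Wo"]);
  q.bo = as<double>(p["bo"]);
  q.gnull = as<vec>(p["g_null"]);
  q.d = q.E.n_rows;
  q.H = q.Wh.n_cols;
  q.A = q.Wa.n_rows;
  q.tdim = q.Wx.n_cols - q.d;
  return q;
}

static List pack_params(const Params& q) {
  return List::create(
    _["emb_entity"]   = wrap(mat(arma::trans(q.E))),
    _["emb_relation"] = wrap(mat(arma::trans(q.R))),
    _["Wx"] = wrap(q.Wx), _["Wh"] = wrap(q.Wh), _["b"] = wrap(q.b),
    _["Wa"] = wrap(q.Wa), _["ba"] = wrap(q.ba), _["ua"] = wrap(q.ua),
    _["Wo"] = wrap(q.Wo), _["bo"] = q.bo, _["g_null"] = wrap(q.gnull));
}

// gradient accumulator with the same shapes
struct Grads {
  mat E, R, Wx, Wh, Wa;
  vec b, ba, ua, Wo, gnull;
  double bo;
  void zeros_like(const Params& q) {
    E.zeros(q.E.n_rows, q.E.n_cols);  R.zeros(q.R.n_rows, q.R.n_cols);
    Wx.zeros(q.Wx.n_rows, q.Wx.n_cols); Wh.zeros(q.Wh.n_rows, q.Wh.n_cols);
    Wa.zeros(q.Wa.n_rows, q.Wa.n_cols);
    b.zeros(q.b.n_elem); ba.zeros(q.ba.n_elem); ua.zeros(q.ua.n_elem);
    Wo.zeros(q.Wo.n_elem); gnull.zeros(q.gnull.n_elem); bo = 0.0;
  }
};

// ---------------------------------------------------------------------------
// forward pass with full trace

struct Trace {
  mat X;                    // nsteps x D inputs
  mat Gi, Gf, Go, Gc;       // nsteps x H gate activations
  mat Cst, Hst;             // nsteps x H cell / output states
  std::vector<vec> alphas;  // per event (empty when no edges)
  std::vector<mat> atanh;   // per event: A x m tanh activations
  vec og;
  arma::uvec amax;          // 0-based winning rows
  double z, y;
};

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static void lstm_step(const Params& q, const vec& x, const vec& hprev,
                      const vec& cprev, vec& i, vec& f, vec& o, vec& cc,
                      vec& C, vec& h) {
  const int H = q.H;
  vec pre = q.Wx * x + q.Wh * hprev + q.b;
  i  = sigmoid(pre.subvec(0, H - 1));
  f  = sigmoid(pre.subvec(H, 2 * H - 1));
  o  = sigmoid(pre.subvec(2 * H, 3 * H - 1));
  cc = arma::tanh(pre.subvec(3 * H, 4 * H - 1));
  C  = f % cprev + i % cc;
  h  = o % arma::tanh(C);
}

// attention over one event's knowledge-graph edges
static void attend(const Params& q, const vec& Cstate, int head,
                   const arma::imat& edges, vec& g, vec& alpha, mat& atanh) {
  const int m = edges.n_rows;
  if (m == 0) { g = q.gnull; alpha.reset(); atanh.reset(); return; }
  const int H = q.H, d = q.d;
  vec scores(m);
  atanh.set_size(q.A, m);
  vec qv(H + 3 * d);
  qv.subvec(0, H - 1) = Cstate;
  qv.subvec(H, H + d - 1) = q.E.col(head);
  for (int j = 0; j < m; ++j) {
    qv.subvec(H + d, H + 2 * d - 1)     = q.R.col(edges(j, 0));
    qv.subvec(H + 2 * d, H + 3 * d - 1) = q.E.col(edges(j, 1));
    vec a = arma::tanh(q.Wa * qv + q.ba);
    atanh.col(j) = a;
    scores[j] = arma::dot(q.ua, a);
  }
  scores -= scores.max();              // softmax, numerically stable
  alpha = arma::exp(scores);
  alpha /= arma::accu(alpha);
  g.zeros(d);
  for (int j = 0; j < m; ++j) g += alpha[j] * q.E.col(edges(j, 1));
}

// adjacency passed as std::vector of integer matrices (m x 2: relation, tail)
typedef std::vector<arma::imat> Adjacency;

static void forward_one(const Params& q, const arma::ivec& codes,
                        const mat& P, const Adjacency& adj, int variant,
                        Trace& tr) {
  const int T = codes.n_elem, H = q.H, d = q.d;
  const int nsteps = (variant == V_NK) ? T : 2 * T;
  const int D = d + q.tdim;
  tr.X.set_size(nsteps, D);
  tr.Gi.set_size(nsteps, H); tr.Gf.set_size(nsteps, H);
  tr.Go.set_size(nsteps, H); tr.Gc.set_size(nsteps, H);
  tr.Cst.set_size(nsteps, H); tr.Hst.set_size(nsteps, H);
  tr.alphas.assign(T, vec());
  tr.atanh.assign(T, mat());

  vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  vec i, f, o, cc, C, h, x(D), g, alpha;
  int s = 0;
  for (int t = 0; t < T; ++t) {
    const int code = codes[t];
    x.subvec(0, d - 1) = q.E.col(code);
    x.subvec(d, D - 1) = arma::trans(P.row(t));
    lstm_step(q, x, hprev, cprev, i, f, o, cc, C, h);
    tr.X.row(s) = x.t(); tr.Gi.row(s) = i.t(); tr.Gf.row(s) = f.t();
    tr.Go.row(s) = o.t(); tr.Gc.row(s) = cc.t();
    tr.Cst.row(s) = C.t(); tr.Hst.row(s) = h.t();
    hprev = h; cprev = C; ++s;
    if (variant != V_NK) {
      mat at;
      attend(q, C, code, adj[code], g, alpha, at);
      tr.alphas[t] = alpha; tr.atanh[t] = at;
      x.subvec(0, d - 1) = g;           // same time encoding reused
      lstm_step(q, x, hprev, cprev, i, f, o, cc, C, h);
      tr.X.row(s) = x.t(); tr.Gi.row(s) = i.t(); tr.Gf.row(s) = f.t();
      tr.Go.row(s) = o.t(); tr.Gc.row(s) = cc.t();
      tr.Cst.row(s) = C.t(); tr.Hst.row(s) = h.t();
      hprev = h; cprev = C; ++s;
    }
  }

  if (variant == V_NP) {
    tr.og.reset(); tr.amax.reset();
    tr.z = arma::dot(q.Wo, tr.Hst.row(nsteps - 1)) + q.bo;
  } else {
    tr.og.set_size(H); tr.amax.set_size(H);
    for (int jd = 0; jd < H; ++jd) {
      double best = tr.Hst(0, jd); uword pos = 0;
      for (int r = 1; r < nsteps; ++r)
        if (tr.Hst(r, jd) > best) { best = tr.Hst(r, jd); pos = r; }
      tr.og[jd] = best; tr.amax[jd] = pos;   // ties keep smallest index
    }
    tr.z = arma::dot(q.Wo, tr.og) + q.bo;
  }
  tr.y = 1.0 / (1.0 + std::exp(-tr.z));
}

// ---------------------------------------------------------------------------
// reverse-mode gradients for one patient; dz = dLoss/dz (y - label for BCE)

static void backward_one(const Params& q, const arma::ivec& codes,
                         const Adjacency& adj, int variant, const Trace& tr,
                         double dz, Grads& gr) {
  const int T = codes.n_elem, H = q.H, d = q.d, D = d + q.tdim;
  const int nsteps = (variant == V_NK) ? T : 2 * T;

  gr.bo += dz;
  mat dH(nsteps, H, arma::fill::zeros);
  if (variant == V_NP) {
    gr.Wo += dz * arma::trans(tr.Hst.row(nsteps - 1));
    dH.row(nsteps - 1) += dz * q.Wo.t();
  } else {
    gr.Wo += dz * tr.og;
    for (int jd = 0; jd < H; ++jd) dH(tr.amax[jd], jd) += dz * q.Wo[jd];
  }

  vec dh_carry(H, arma::fill::zeros), dC_carry(H, arma::fill::zeros);
  for (int s = nsteps - 1; s >= 0; --s) {
    vec dh = arma::trans(dH.row(s)) + dh_carry;
    vec o  = arma::trans(tr.Go.row(s)), i = arma::trans(tr.Gi.row(s));
    vec f  = arma::trans(tr.Gf.row(s)), cc = arma::trans(tr.Gc.row(s));
    vec C  = arma::trans(tr.Cst.row(s));
    vec cprev = (s == 0) ? vec(H, arma::fill::zeros)
                         : vec(arma::trans(tr.Cst.row(s - 1)));
    vec hprev = (s == 0) ? vec(H, arma::fill::zeros)
                         : vec(arma::trans(tr.Hst.row(s - 1)));
    vec tc = arma::tanh(C);
    vec dC = dC_carry + dh % o % (1.0 - tc % tc);
    vec do_ = dh % tc;
    vec di = dC % cc, dcc = dC % i, df = dC % cprev;
    dC_carry = dC % f;

    vec dpre(4 * H);
    dpre.subvec(0, H - 1)         = di % i % (1.0 - i);
    dpre.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    dpre.subvec(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    dpre.subvec(3 * H, 4 * H - 1) = dcc % (1.0 - cc % cc);

    vec x = arma::trans(tr.X.row(s));
    gr.Wx += dpre * x.t();
    gr.Wh += dpre * hprev.t();
    gr.b  += dpre;
    vec dx = q.Wx.t() * dpre;
    dh_carry = q.Wh.t() * dpre;

    const bool gstep = (variant != V_NK) && (s % 2 == 1);
    if (gstep) {
      // dx[0:d] is the gradient wrt the attention result g_t
      const int t = s / 2;
      const int code = codes[t];
      vec dg = dx.subvec(0, d - 1);
      const arma::imat& edges = adj[code];
      const int m = edges.n_rows;
      if (m == 0) {
        gr.gnull += dg;
      } else {
        const vec& alpha = tr.alphas[t];
        const mat& at = tr.atanh[t];
        vec Cprev_att = arma::trans(tr.Cst.row(s - 1)); // C_{2t-1}
        vec dalpha(m), dsc(m);
        for (int j = 0; j < m; ++j) {
          gr.E.col(edges(j, 1)) += alpha[j] * dg;
          dalpha[j] = arma::dot(dg, q.E.col(edges(j, 1)));
        }
        const double adot = arma::dot(alpha, dalpha);
        for (int j = 0; j < m; ++j) dsc[j] = alpha[j] * (dalpha[j] - adot);
        vec qv(H + 3 * d);
        qv.subvec(0, H - 1) = Cprev_att;
        qv.subvec(H, H + d - 1) = q.E.col(code);
        for (int j = 0; j < m; ++j) {
          qv.subvec(H + d, H + 2 * d - 1)     = q.R.col(edges(j, 0));
          qv.subvec(H + 2 * d, H + 3 * d - 1) = q.E.col(edges(j, 1));
          vec a = at.col(j);
          gr.ua += dsc[j] * a;
          vec dprea = (dsc[j] * q.ua) % (1.0 - a % a);
          gr.Wa += dprea * qv.t();
          gr.ba += dprea;
          vec dq = q.Wa.t() * dprea;
          dC_carry += dq.subvec(0, H - 1);          // into C_{2t-1}
          gr.E.col(code)        += dq.subvec(H, H + d - 1);
          gr.R.col(edges(j, 0)) += dq.subvec(H + d, H + 2 * d - 1);
          gr.E.col(edges(j, 1)) += dq.subvec(H + 2 * d, H + 3 * d - 1);
        }
      }
    } else {
      // event step: dx[0:d] flows to the code embedding
      const int t = (variant == V_NK) ? s : s / 2;
      gr.E.col(codes[t]) += dx.subvec(0, d - 1);
    }
  }
}

// ---------------------------------------------------------------------------
// exported single-patient forward

static Adjacency build_adj(const List& adjList) {
  Adjacency adj(adjList.size());
  for (int i = 0; i < adjList.size(); ++i) {
    IntegerMatrix m = adjList[i];
    arma::imat am(m.nrow(), 2);
    for (int r = 0; r < m.nrow(); ++r) { am(r, 0) = m(r, 0); am(r, 1) = m(r, 1); }
    adj[i] = am;
  }
  return adj;
}

// [[Rcpp::export]]
List cpp_forward(List params, IntegerVector codes0, NumericVector times,
                 List adjList, int variant) {
  Params q = unpack_params(params);
  Adjacency adj = build_adj(adjList);
  arma::ivec codes(codes0.size());
  for (int i = 0; i < codes0.size(); ++i) codes[i] = codes0[i];
  vec tv(times.begin(), times.size());
  mat P = time_encode_mat(tv, q.tdim);
  Trace tr;
  forward_one(q, codes, P, adj, variant, tr);
  List alphas(codes.n_elem);
  for (uword t = 0; t < codes.n_elem; ++t) alphas[t] = wrap(tr.alphas[t]);
  List out = List::create(
    _["H"] = wrap(tr.Hst), _["C"] = wrap(tr.Cst), _["alphas"] = alphas,
    _["z"] = tr.z, _["y"] = tr.y);
  if (variant == V_NP) {
    out["o_g"] = R_NilValue; out["pool_argmax"] = R_NilValue;
  } else {
    out["o_g"] = wrap(tr.og);
    IntegerVector am(tr.amax.n_elem);
    for (uword j = 0; j < tr.amax.n_elem; ++j) am[j] = tr.amax[j] + 1; // 1-based
    out["pool_argmax"] = am;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_predict(List params, List patients, List adjList, int variant) {
  Params q = unpack_params(params);
  Adjacency adj = build_adj(adjList);
  const int n = patients.size();
  NumericVector prob(n), logit(n);
  NumericMatrix pooled(n, q.H);
  for (int i = 0; i < n; ++i) {
    List pat = patients[i];
    IntegerVector codes0 = pat["codes"];
    NumericVector times = pat["times"];
    arma::ivec codes(codes0.size());
    for (int k = 0; k < codes0.size(); ++k) codes[k] = codes0[k];
    vec tv(times.begin(), times.size());
    mat P = time_encode_mat(tv, q.tdim);
    Trace tr;
    forward_one(q, codes, P, adj, variant, tr);
    prob[i] = tr.y; logit[i] = tr.z;
    if (variant != V_NP)
      for (int jd = 0; jd < q.H; ++jd) pooled(i, jd) = tr.og[jd];
    else
      for (int jd = 0; jd < q.H; ++jd) pooled(i, jd) = tr.Hst(tr.Hst.n_rows - 1, jd);
  }
  return List::create(_["prob"] = prob, _["logit"] = logit,
                      _["pooled"] = pooled);
}

// ---------------------------------------------------------------------------
// Adam training loop

struct Adam {
  mat mE, vE, mR, vR, mWx, vWx, mWh, vWh, mWa, vWa;
  vec mb, vb, mba, vba, mua, vua, mWo, vWo, mg, vg;
  double mbo, vbo;
  long t;
  void init(const Params& q) {
    mE.zeros(arma::size(q.E)); vE.zeros(arma::size(q.E));
    mR.zeros(arma::size(q.R)); vR.zeros(arma::size(q.R));
    mWx.zeros(arma::size(q.Wx)); vWx.zeros(arma::size(q.Wx));
    mWh.zeros(arma::size(q.Wh)); vWh.zeros(arma::size(q.Wh));
    mWa.zeros(arma::size(q.Wa)); vWa.zeros(arma::size(q.Wa));
    mb.zeros(q.b.n_elem); vb.zeros(q.b.n_elem);
    mba.zeros(q.ba.n_elem); vba.zeros(q.ba.n_elem);
    mua.zeros(q.ua.n_elem); vua.zeros(q.ua.n_elem);
    mWo.zeros(q.Wo.n_elem); vWo.zeros(q.Wo.n_elem);
    mg.zeros(q.gnull.n_elem); vg.zeros(q.gnull.n_elem);
    mbo = vbo = 0.0; t = 0;
  }
};

template <typename T>
static void adam_update(T& w, T& m, T& v, const T& g, double lr,
                        double b1, double b2, double eps, double bc1,
                        double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

static void adam_update_scalar(double& w, double& m, double& v, double g,
                               double lr, double b1, double b2, double eps,
                               double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * g * g;
  w -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
}

// plan: list over epochs; each epoch a list of integer vectors of 0-based
// patient indices (the batches, already shuffled/paired by the caller).
// [[Rcpp::export]]
List cpp_train(List params, List patients, List adjList, int variant,
               List plan, double lr, bool fine_tune_kg, double clip,
               double beta1, double beta2, double eps) {
  Params q = unpack_params(params);
  Adjacency adj = build_adj(adjList);

  const int n = patients.size();
  std::vector<arma::ivec> codes(n);
  std::vector<mat> P(n);
  std::vector<double> label(n);
  for (int i = 0; i < n; ++i) {
    List pat = patients[i];
    IntegerVector c0 = pat["codes"];
    NumericVector tm = pat["times"];
    arma::ivec cv(c0.size());
    for (int k = 0; k < c0.size(); ++k) cv[k] = c0[k];
    codes[i] = cv;
    vec tv(tm.begin(), tm.size());
    P[i] = time_encode_mat(tv, q.tdim);
    label[i] = as<double>(pat["label"]);
  }

  Adam ad; ad.init(q);
  Grads gr;
  const int n_epochs = plan.size();
  NumericVector loss_hist(n_epochs);
  const bool train_att = (variant != V_NK);

  for (int ep = 0; ep < n_epochs; ++ep) {
    List batches = plan[ep];
    double ep_loss = 0.0; long ep_n = 0;
    for (int bi = 0; bi < batches.size(); ++bi) {
      IntegerVector idx = batches[bi];
      const int bn = idx.size();
      if (bn == 0) continue;
      gr.zeros_like(q);
      for (int k = 0; k < bn; ++k) {
        const int i = idx[k];
        Trace tr;
        forward_one(q, codes[i], P[i], adj, variant, tr);
        const double yc = std::min(std::max(tr.y, 1e-12), 1.0 - 1e-12);
        const double li = -(label[i] * std::log(yc) +
                            (1.0 - label[i]) * std::log(1.0 - yc));
        if (!std::isfinite(li))
          stop("non-finite loss at epoch %d, batch %d", ep + 1, bi + 1);
        ep_loss += li; ++ep_n;
        backward_one(q, codes[i], adj, variant, tr, tr.y - label[i], gr);
      }
      // mean gradient over the batch
      const double inv = 1.0 / bn;
      gr.E *= inv; gr.R *= inv; gr.Wx *= inv; gr.Wh *= inv; gr.Wa *= inv;
      gr.b *= inv; gr.ba *= inv; gr.ua *= inv; gr.Wo *= inv;
      gr.gnull *= inv; gr.bo *= inv;
      // global-norm clip for stability on long sequences
      double ss = arma::accu(gr.Wx % gr.Wx) + arma::accu(gr.Wh % gr.Wh) +
                  arma::accu(gr.b % gr.b) + arma::accu(gr.Wo % gr.Wo) +
                  gr.bo * gr.bo + arma::accu(gr.E % gr.E) +
                  arma::accu(gr.R % gr.R) + arma::accu(gr.Wa % gr.Wa) +
                  arma::accu(gr.ba % gr.ba) + arma::accu(gr.ua % gr.ua) +
                  arma::accu(gr.gnull % gr.gnull);
      const double gnorm = std::sqrt(ss);
      if (clip > 0 && gnorm > clip) {
        const double sc = clip / gnorm;
        gr.E *= sc; gr.R *= sc; gr.Wx *= sc; gr.Wh *= sc; gr.Wa *= sc;
        gr.b *= sc; gr.ba *= sc; gr.ua *= sc; gr.Wo *= sc;
        gr.gnull *= sc; gr.bo *= sc;
      }
      ad.t += 1;
      const double bc1 = 1.0 - std::pow(beta1, (double)ad.t);
      const double bc2 = 1.0 - std::pow(beta2, (double)ad.t);
      adam_update(q.Wx, ad.mWx, ad.vWx, gr.Wx, lr, beta1, beta2, eps, bc1, bc2);
      adam_update(q.Wh, ad.mWh, ad.vWh, gr.Wh, lr, beta1, beta2, eps, bc1, bc2);
      adam_update(q.b,  ad.mb,  ad.vb,  gr.b,  lr, beta1, beta2, eps, bc1, bc2);
      adam_update(q.Wo, ad.mWo, ad.vWo, gr.Wo, lr, beta1, beta2, eps, bc1, bc2);
      adam_update_scalar(q.bo, ad.mbo, ad.vbo, gr.bo, lr, beta1, beta2, eps,
                         bc1, bc2);
      if (train_att) {
        adam_update(q.Wa, ad.mWa, ad.vWa, gr.Wa, lr, beta1, beta2, eps, bc1, bc2);
        adam_update(q.ba, ad.mba, ad.vba, gr.ba, lr, beta1, beta2, eps, bc1, bc2);
        adam_update(q.ua, ad.mua, ad.vua, gr.ua, lr, beta1, beta2, eps, bc1, bc2);
        adam_update(q.gnull, ad.mg, ad.vg, gr.gnull, lr, beta1, beta2, eps,
                    bc1, bc2);
      }
      if (fine_tune_kg) {
        adam_update(q.E, ad.mE, ad.vE, gr.E, lr, beta1, beta2, eps, bc1, bc2);
        if (train_att)
          adam_update(q.R, ad.mR, ad.vR, gr.R, lr, beta1, beta2, eps, bc1, bc2);
      }
    }
    loss_hist[ep] = ep_n > 0 ? ep_loss / ep_n : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack_params(q),
                      _["loss_history"] = loss_hist);
}
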