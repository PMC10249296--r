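// Twin-GNN reaction encoder and pairwise scorer.
//
// Each side (reactants, product) runs an attention-gated message-passing
// network: per directed edge a sigmoid gate computed from both endpoint
// states and the bond features modulates the message; node updates are
// residual + ReLU. A global attention readout (softmax over nodes, multi-head,
// iterated T steps through a tanh update) pools each graph to a vector; the
// reaction representation is the concatenation of the two sides, and the
// scorer is two affine layers with a ReLU between. Forward and backward are
// written out by hand; gradients are checked against finite differences in
// the test suite.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Graph {
  mat X;        // d_in x n
  uvec src, dst; // directed edges (message dst <- src), length 2m
  mat F;        // d_e x 2m
};

struct RecordGraphs { Graph react, prod; };

static Graph graph_from_list(const List& g, const char* xk, const char* ek, const char* fk) {
  Graph out;
  mat Xr = as<mat>(g[xk]);      // n x d_in from R
  out.X = Xr.t();
  IntegerMatrix E = g[ek];      // m x 2, 1-based
  int m = E.nrow();
  mat Fr = as<mat>(g[fk]);      // m x d_bond
  out.src.set_size(2 * m); out.dst.set_size(2 * m);
  out.F.set_size(Fr.n_cols, 2 * m);
  for (int k = 0; k < m; ++k) {
    int a = E(k, 0) - 1, b = E(k, 1) - 1;
    out.dst[2 * k] = a;     out.src[2 * k] = b;
    out.dst[2 * k + 1] = b; out.src[2 * k + 1] = a;
    out.F.col(2 * k) = Fr.row(k).t();
    out.F.col(2 * k + 1) = Fr.row(k).t();
  }
  return out;
}

// [[Rcpp::export]]
SEXP rr_store_create(List records) {
  auto* store = new std::vector<RecordGraphs>();
  store->reserve(records.size());
  for (int i = 0; i < records.size(); ++i) {
    List r = records[i];
    RecordGraphs rg;
    rg.react = graph_from_list(r, "xr", "er", "fr");
    rg.prod = graph_from_list(r, "xp", "ep", "fp");
    store->push_back(std::move(rg));
  }
  XPtr<std::vector<RecordGraphs>> ptr(store, true);
  return ptr;
}

// [[Rcpp::export]]
int rr_store_size(SEXP store_) {
  XPtr<std::vector<RecordGraphs>> store(store_);
  return (int)store->size();
}

struct EncParams {
  mat Win; vec bin;
  std::vector<mat> Wg, Wm, Wf, Wu;
  std::vector<vec> bg, bm, bu;
  std::vector<mat> Wq, Wz;
  std::vector<vec> bz;
};

struct Params {
  int h, L, T, A;
  EncParams enc[2];           // 0 = reactant side, 1 = product side
  mat W1; vec b1; mat w2; double b2;
};

static std::string pname(int side, const char* base, int idx) {
  std::string s = side == 0 ? "r_" : "p_";
  s += base;
  if (idx >= 0) s += std::to_string(idx + 1);
  return s;
}

static Params unpack(const List& plist) {
  Params P;
  IntegerVector dims = plist["dims"];
  P.h = dims[0]; P.L = dims[1]; P.T = dims[2]; P.A = dims[3];
  for (int s = 0; s < 2; ++s) {
    EncParams& e = P.enc[s];
    e.Win = as<mat>(plist[pname(s, "Win", -1)]);
    e.bin = as<vec>(plist[pname(s, "bin", -1)]);
    for (int l = 0; l < P.L; ++l) {
      e.Wg.push_back(as<mat>(plist[pname(s, "Wg", l)]));
      e.bg.push_back(as<vec>(plist[pname(s, "bg", l)]));
      e.Wm.push_back(as<mat>(plist[pname(s, "Wm", l)]));
      e.Wf.push_back(as<mat>(plist[pname(s, "Wf", l)]));
      e.bm.push_back(as<vec>(plist[pname(s, "bm", l)]));
      e.Wu.push_back(as<mat>(plist[pname(s, "Wu", l)]));
      e.bu.push_back(as<vec>(plist[pname(s, "bu", l)]));
    }
    for (int t = 0; t < P.T; ++t) {
      e.Wq.push_back(as<mat>(plist[pname(s, "Wq", t)]));
      e.Wz.push_back(as<mat>(plist[pname(s, "Wz", t)]));
      e.bz.push_back(as<vec>(plist[pname(s, "bz", t)]));
    }
  }
  P.W1 = as<mat>(plist["sc_W1"]);
  P.b1 = as<vec>(plist["sc_b1"]);
  P.w2 = as<mat>(plist["sc_w2"]);
  P.b2 = as<mat>(plist["sc_b2"])(0, 0);
  return P;
}

struct EncGrads {
  mat Win; vec bin;
  std::vector<mat> Wg, Wm, Wf, Wu;
  std::vector<vec> bg, bm, bu;
  std::vector<mat> Wq, Wz;
  std::vector<vec> bz;
  void init(const EncParams& e) {
    Win.zeros(arma::size(e.Win)); bin.zeros(e.bin.n_elem);
    for (size_t l = 0; l < e.Wg.size(); ++l) {
      Wg.push_back(mat(arma::size(e.Wg[l]), arma::fill::zeros));
      bg.push_back(vec(e.bg[l].n_elem, arma::fill::zeros));
      Wm.push_back(mat(arma::size(e.Wm[l]), arma::fill::zeros));
      Wf.push_back(mat(arma::size(e.Wf[l]), arma::fill::zeros));
      bm.push_back(vec(e.bm[l].n_elem, arma::fill::zeros));
      Wu.push_back(mat(arma::size(e.Wu[l]), arma::fill::zeros));
      bu.push_back(vec(e.bu[l].n_elem, arma::fill::zeros));
    }
    for (size_t t = 0; t < e.Wq.size(); ++t) {
      Wq.push_back(mat(arma::size(e.Wq[t]), arma::fill::zeros));
      Wz.push_back(mat(arma::size(e.Wz[t]), arma::fill::zeros));
      bz.push_back(vec(e.bz[t].n_elem, arma::fill::zeros));
    }
  }
};

struct Grads {
  EncGrads enc[2];
  mat W1; vec b1; mat w2; double b2;
  void init(const Params& P) {
    enc[0].init(P.enc[0]); enc[1].init(P.enc[1]);
    W1.zeros(arma::size(P.W1)); b1.zeros(P.b1.n_elem);
    w2.zeros(arma::size(P.w2)); b2 = 0.0;
  }
};

struct Cache {
  std::vector<mat> H;       // L+1, post-activation (h x n)
  std::vector<mat> M;       // L, accumulated messages (h x n)
  std::vector<mat> G, Am;   // L, per-edge gates and linear parts (h x 2m)
  vec g0;
  std::vector<vec> g;       // T
  std::vector<mat> alpha;   // T, n x A
  std::vector<mat> cheads;  // T, h x A
};

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static vec encode_forward(const EncParams& P, int T, int A, const Graph& g, Cache& C) {
  int n = g.X.n_cols;
  int L = (int)P.Wg.size();
  mat H = P.Win * g.X;
  H.each_col() += P.bin;
  H = arma::clamp(H, 0.0, arma::datum::inf);   // ReLU
  C.H.push_back(H);
  int me = g.src.n_elem;
  for (int l = 0; l < L; ++l) {
    mat M(P.bin.n_elem, n, arma::fill::zeros);
    mat G, Am;
    if (me > 0) {
      mat Hd = H.cols(g.dst), Hs = H.cols(g.src);
      mat U = arma::join_cols(arma::join_cols(Hd, Hs), g.F);
      G = P.Wg[l] * U; G.each_col() += P.bg[l]; G = sigmoid_m(G);
      Am = P.Wm[l] * Hs + P.Wf[l] * g.F; Am.each_col() += P.bm[l];
      mat Msg = G % Am;
      for (int k = 0; k < me; ++k) M.col(g.dst[k]) += Msg.col(k);
    }
    C.G.push_back(G); C.Am.push_back(Am); C.M.push_back(M);
    mat Hn = H + P.Wu[l] * M;
    Hn.each_col() += P.bu[l];
    Hn = arma::clamp(Hn, 0.0, arma::datum::inf);
    H = Hn;
    C.H.push_back(H);
  }
  vec gv = arma::mean(H, 1);
  C.g0 = gv;
  for (int t = 0; t < T; ++t) {
    vec qf = P.Wq[t] * gv;                       // (A*h)
    mat alpha(n, A), cheads(H.n_rows, A);
    for (int a = 0; a < A; ++a) {
      vec qa = qf.subvec(a * H.n_rows, (a + 1) * H.n_rows - 1);
      vec e = H.t() * qa;
      e -= e.max();
      vec al = arma::exp(e); al /= arma::accu(al);
      alpha.col(a) = al;
      cheads.col(a) = H * al;
    }
    vec c = arma::mean(cheads, 1);
    vec cat = arma::join_cols(gv, c);
    vec gt = arma::tanh(P.Wz[t] * cat + P.bz[t]);
    C.alpha.push_back(alpha); C.cheads.push_back(cheads); C.g.push_back(gt);
    gv = gt;
  }
  return gv;
}

// backward through one encoder given d(output embedding); accumulates into G
static void encode_backward(const EncParams& P, int T, int A, const Graph& g,
                            const Cache& C, vec dgv, EncGrads& Gr) {
  int n = g.X.n_cols;
  int h = P.bin.n_elem;
  int L = (int)P.Wg.size();
  const mat& HL = C.H[L];
  mat dH(h, n, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec gprev = (t == 0) ? C.g0 : C.g[t - 1];
    vec c = arma::mean(C.cheads[t], 1);
    vec cat = arma::join_cols(gprev, c);
    vec gt = C.g[t];
    vec du = dgv % (1.0 - gt % gt);
    Gr.Wz[t] += du * cat.t();
    Gr.bz[t] += du;
    vec dcat = P.Wz[t].t() * du;
    vec dgprev = dcat.subvec(0, h - 1);
    vec dc = dcat.subvec(h, 2 * h - 1);
    vec qf = P.Wq[t] * gprev;
    vec dqf(A * h, arma::fill::zeros);
    for (int a = 0; a < A; ++a) {
      vec dca = dc / (double)A;
      vec al = C.alpha[t].col(a);
      dH += dca * al.t();
      vec dal = HL.t() * dca;
      vec de = al % (dal - arma::dot(al, dal));
      vec qa = qf.subvec(a * h, (a + 1) * h - 1);
      dqf.subvec(a * h, (a + 1) * h - 1) = HL * de;
      dH += qa * de.t();
    }
    Gr.Wq[t] += dqf * gprev.t();
    dgprev += P.Wq[t].t() * dqf;
    dgv = dgprev;
  }
  // g0 = row means of HL
  dH.each_col() += dgv / (double)n;

  int me = g.src.n_elem;
  for (int l = L - 1; l >= 0; --l) {
    const mat& Hprev = C.H[l];
    const mat& Hout = C.H[l + 1];
    mat dpre = dH % arma::conv_to<mat>::from(Hout > 0.0);
    Gr.bu[l] += arma::sum(dpre, 1);
    Gr.Wu[l] += dpre * C.M[l].t();
    mat dM = P.Wu[l].t() * dpre;
    mat dHprev = dpre;   // residual path
    if (me > 0) {
      const mat& G = C.G[l];
      const mat& Am = C.Am[l];
      mat dMsg(h, me);
      for (int k = 0; k < me; ++k) dMsg.col(k) = dM.col(g.dst[k]);
      mat dG = dMsg % Am;
      mat dA = dMsg % G;
      mat Hs = Hprev.cols(g.src);
      Gr.Wm[l] += dA * Hs.t();
      Gr.Wf[l] += dA * g.F.t();
      Gr.bm[l] += arma::sum(dA, 1);
      mat dHs_m = P.Wm[l].t() * dA;
      mat ds = dG % G % (1.0 - G);
      mat Hd = Hprev.cols(g.dst);
      mat U = arma::join_cols(arma::join_cols(Hd, Hs), g.F);
      Gr.Wg[l] += ds * U.t();
      Gr.bg[l] += arma::sum(ds, 1);
      mat dU = P.Wg[l].t() * ds;     // (2h+d_e) x me
      for (int k = 0; k < me; ++k) {
        dHprev.col(g.dst[k]) += dU.col(k).subvec(0, h - 1);
        dHprev.col(g.src[k]) += dU.col(k).subvec(h, 2 * h - 1) + dHs_m.col(k);
      }
    }
    dH = dHprev;
  }
  mat dpre0 = dH % arma::conv_to<mat>::from(C.H[0] > 0.0);
  Gr.Win += dpre0 * g.X.t();
  Gr.bin += arma::sum(dpre0, 1);
}

static double score_forward(const Params& P, const RecordGraphs& rg,
                            Cache& Cr, Cache& Cp, vec& z, vec& a1) {
  vec gr = encode_forward(P.enc[0], P.T, P.A, rg.react, Cr);
  vec gp = encode_forward(P.enc[1], P.T, P.A, rg.prod, Cp);
  z = arma::join_cols(gr, gp);
  vec u1 = P.W1 * z + P.b1;
  a1 = arma::clamp(u1, 0.0, arma::datum::inf);
  return arma::dot(P.w2.row(0).t(), a1) + P.b2;
}

// backprop d(score) through scorer and both encoders
static void score_backward(const Params& P, const RecordGraphs& rg,
                           const Cache& Cr, const Cache& Cp,
                           const vec& z, const vec& a1, double ds, Grads& G) {
  int h2 = P.W1.n_cols;
  G.b2 += ds;
  G.w2 += ds * a1.t();
  vec da1 = ds * P.w2.row(0).t();
  vec du1 = da1 % arma::conv_to<vec>::from(a1 > 0.0);
  G.W1 += du1 * z.t();
  G.b1 += du1;
  vec dz = P.W1.t() * du1;
  vec dgr = dz.subvec(0, h2 / 2 - 1);
  vec dgp = dz.subvec(h2 / 2, h2 - 1);
  encode_backward(P.enc[0], P.T, P.A, rg.react, Cr, dgr, G.enc[0]);
  encode_backward(P.enc[1], P.T, P.A, rg.prod, Cp, dgp, G.enc[1]);
}

// [[Rcpp::export]]
NumericVector rr_score_ids(List params, SEXP store_, IntegerVector ids) {
  XPtr<std::vector<RecordGraphs>> store(store_);
  Params P = unpack(params);
  NumericVector out(ids.size());
  for (int i = 0; i < ids.size(); ++i) {
    Cache Cr, Cp; vec z, a1;
    out[i] = score_forward(P, (*store)[ids[i] - 1], Cr, Cp, z, a1);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rr_encode_id(List params, SEXP store_, int id) {
  XPtr<std::vector<RecordGraphs>> store(store_);
  Params P = unpack(params);
  Cache Cr, Cp;
  vec gr = encode_forward(P.enc[0], P.T, P.A, (*store)[id - 1].react, Cr);
  vec gp = encode_forward(P.enc[1], P.T, P.A, (*store)[id - 1].prod, Cp);
  vec z = arma::join_cols(gr, gp);
  return NumericVector(z.begin(), z.end());
}

static inline double log_sigmoid(double x) {
  return x >= 0.0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

static List grads_to_list(const Params& P, const Grads& G, double scale) {
  List out;
  for (int s = 0; s < 2; ++s) {
    const EncGrads& e = G.enc[s];
    out[pname(s, "Win", -1)] = wrap(mat(e.Win * scale));
    out[pname(s, "bin", -1)] = wrap(mat(e.bin * scale));
    for (int l = 0; l < P.L; ++l) {
      out[pname(s, "Wg", l)] = wrap(mat(e.Wg[l] * scale));
      out[pname(s, "bg", l)] = wrap(mat(e.bg[l] * scale));
      out[pname(s, "Wm", l)] = wrap(mat(e.Wm[l] * scale));
      out[pname(s, "Wf", l)] = wrap(mat(e.Wf[l] * scale));
      out[pname(s, "bm", l)] = wrap(mat(e.bm[l] * scale));
      out[pname(s, "Wu", l)] = wrap(mat(e.Wu[l] * scale));
      out[pname(s, "bu", l)] = wrap(mat(e.bu[l] * scale));
    }
    for (int t = 0; t < P.T; ++t) {
      out[pname(s, "Wq", t)] = wrap(mat(e.Wq[t] * scale));
      out[pname(s, "Wz", t)] = wrap(mat(e.Wz[t] * scale));
      out[pname(s, "bz", t)] = wrap(mat(e.bz[t] * scale));
    }
  }
  out["sc_W1"] = wrap(mat(G.W1 * scale));
  out["sc_b1"] = wrap(mat(G.b1 * scale));
  out["sc_w2"] = wrap(mat(G.w2 * scale));
  out["sc_b2"] = wrap(mat(1, 1, arma::fill::value(G.b2 * scale)));
  return out;
}

// Mean pairwise label-smoothed CE loss, pairwise accuracy and mean gradients
// over a batch of (positive, negative) record pairs. `dropout` (if > 0)
// applies inverted dropout to the scorer hidden layer during this call only.
// [[Rcpp::export]]
List rr_pair_batch_grad(List params, SEXP store_, IntegerVector pos,
                        IntegerVector neg, double eps,
                        double dropout = 0.0, int seed = 0) {
  if (pos.size() != neg.size()) stop("pos/neg length mismatch");
  XPtr<std::vector<RecordGraphs>> store(store_);
  Params P = unpack(params);
  Grads G; G.init(P);
  double loss = 0.0; int correct = 0;
  int B = pos.size();
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int c = P.b1.n_elem;
  for (int i = 0; i < B; ++i) {
    const RecordGraphs& rp = (*store)[pos[i] - 1];
    const RecordGraphs& rn = (*store)[neg[i] - 1];
    Cache Cr1, Cp1, Cr2, Cp2; vec z1, a11, z2, a12;
    double s1 = score_forward(P, rp, Cr1, Cp1, z1, a11);
    double s2 = score_forward(P, rn, Cr2, Cp2, z2, a12);
    vec m1(c, arma::fill::ones), m2(c, arma::fill::ones);
    if (dropout > 0.0) {
      for (int k = 0; k < c; ++k) {
        m1[k] = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        m2[k] = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      }
      vec a11d = a11 % m1, a12d = a12 % m2;
      s1 = arma::dot(P.w2.row(0).t(), a11d) + P.b2;
      s2 = arma::dot(P.w2.row(0).t(), a12d) + P.b2;
    }
    double delta = s1 - s2;
    loss += -(1.0 - eps) * log_sigmoid(delta) - eps * log_sigmoid(-delta);
    if (delta > 0) ++correct;
    double dd = 1.0 / (1.0 + std::exp(-delta)) - (1.0 - eps);  // dL/ds1
    if (dropout > 0.0) {
      // fold the dropout mask into the scorer backward by scaling a1
      vec a11d = a11 % m1, a12d = a12 % m2;
      // scorer backward with masked activations
      G.b2 += dd; G.w2 += dd * a11d.t();
      vec da1 = (dd * P.w2.row(0).t()) % m1;
      vec du1 = da1 % arma::conv_to<vec>::from(a11 > 0.0);
      G.W1 += du1 * z1.t(); G.b1 += du1;
      vec dz = P.W1.t() * du1;
      encode_backward(P.enc[0], P.T, P.A, rp.react, Cr1,
                      dz.subvec(0, dz.n_elem / 2 - 1), G.enc[0]);
      encode_backward(P.enc[1], P.T, P.A, rp.prod, Cp1,
                      dz.subvec(dz.n_elem / 2, dz.n_elem - 1), G.enc[1]);
      G.b2 += -dd; G.w2 += -dd * a12d.t();
      vec da2 = (-dd * P.w2.row(0).t()) % m2;
      vec du2 = da2 % arma::conv_to<vec>::from(a12 > 0.0);
      G.W1 += du2 * z2.t(); G.b1 += du2;
      vec dz2 = P.W1.t() * du2;
      encode_backward(P.enc[0], P.T, P.A, rn.react, Cr2,
                      dz2.subvec(0, dz2.n_elem / 2 - 1), G.enc[0]);
      encode_backward(P.enc[1], P.T, P.A, rn.prod, Cp2,
                      dz2.subvec(dz2.n_elem / 2, dz2.n_elem - 1), G.enc[1]);
    } else {
      score_backward(P, rp, Cr1, Cp1, z1, a11, dd, G);
      score_backward(P, rn, Cr2, Cp2, z2, a12, -dd, G);
    }
  }
  double scale = 1.0 / (double)B;
  return List::create(
    _["loss"] = loss * scale,
    _["accuracy"] = (double)correct * scale,
    _["grads"] = grads_to_list(P, G, scale));
}
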