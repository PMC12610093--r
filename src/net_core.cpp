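// Compiled training / inference core of the coupled cross-attention network.
//
// The R level owns configuration, parameter initialisation and the module
// surface (a readable reference forward pass); this file implements the
// batched forward pass, manual backpropagation and Adam loop used for
// training and bulk prediction. Parameter memory layout must match
// param_layout() on the R side exactly.
//
// Everything is templated on the element type: prediction and the gradient
// interface run in double (and match the R reference to machine precision;
// the test suite cross-checks both implementations and the analytic
// gradients against finite differences), while the training loop runs the
// same code in single precision — the 512 x 512 attention matrices make the
// network memory-bandwidth-bound, and halving the element width roughly
// doubles throughput at a precision far beyond what SGD noise resolves.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

static const double BN_EPS = 1e-5;
static const double LN_EPS = 1e-5;
static const double BN_MOM = 0.1;

struct Cfg {
  int ch, t, k, h, L, m, fc_hidden;
  double fs, dropout;
  int fusion;   // 0 cca, 1 sum, 2 cat, 3 atten
  int variant;  // 0 full, 1 no_lfem, 2 no_gfem
  int kt, kc, H2, W1, Hp, Wp, npos;
};

static Cfg parse_cfg(const Rcpp::List& cl) {
  Cfg c;
  c.ch = Rcpp::as<int>(cl["channels"]);
  c.t  = Rcpp::as<int>(cl["timepoints"]);
  c.k  = Rcpp::as<int>(cl["k"]);
  c.h  = Rcpp::as<int>(cl["h"]);
  c.L  = Rcpp::as<int>(cl["seq_len"]);
  c.m  = Rcpp::as<int>(cl["n_classes"]);
  c.fc_hidden = Rcpp::as<int>(cl["fc_hidden"]);
  c.fs = Rcpp::as<double>(cl["sampling_rate"]);
  c.dropout = Rcpp::as<double>(cl["dropout"]);
  std::string fus = Rcpp::as<std::string>(cl["fusion"]);
  std::string var = Rcpp::as<std::string>(cl["variant"]);
  c.fusion  = fus == "cca" ? 0 : fus == "sum" ? 1 : fus == "cat" ? 2 : 3;
  c.variant = var == "full" ? 0 : var == "no_lfem" ? 1 : 2;
  c.kt = (int)(c.fs / 10.0);
  c.kc = c.ch / 2;
  c.H2 = c.ch - c.kc + 1;
  c.W1 = c.t - c.kt + 1;
  c.Hp = c.H2 / 4;
  c.Wp = c.W1 / 4;
  c.npos = c.Hp * c.Wp;
  return c;
}

// ---------------------------------------------------------------- layout --

struct PDef { std::string name; int nr, nc; };

static std::vector<PDef> make_layout(const Cfg& c) {
  std::vector<PDef> L;
  auto add = [&](const std::string& n, int nr, int nc) { L.push_back({n, nr, nc}); };
  const int k = c.k;
  if (c.variant != 1) {
    add("conv_t1_w", c.kt, k);
    add("conv_t2_w", k * c.kc, k);
    add("bn_t_gamma", k, 1); add("bn_t_beta", k, 1);
    add("conv_s1_w", c.kc, k);
    add("conv_s2_w", k * c.kt, k);
    add("bn_s_gamma", k, 1); add("bn_s_beta", k, 1);
  } else {
    add("proj_t_w", 1, k); add("proj_t_b", k, 1);
    add("proj_s_w", 1, k); add("proj_s_b", k, 1);
  }
  if (c.fusion == 0) {
    for (const char* dir : {"ts", "st"}) {
      for (const char* role : {"q", "k", "v"}) {
        add(std::string("W") + role + "_" + dir, k, k);
        add(std::string("b") + role + "_" + dir, k, 1);
      }
    }
    add("alpha", 1, 1); add("beta", 1, 1);
    add("ln_gain", k, 1); add("ln_shift", k, 1);
  } else if (c.fusion == 2) {
    add("Wcat", 2 * k, k); add("bcat", k, 1);
  } else if (c.fusion == 3) {
    add("Wat", 2 * k, 2); add("bat", 2, 1);
  }
  if (c.variant != 2) {
    for (const char* role : {"gq", "gk", "gv", "go"}) {
      add(std::string("W") + role, k, k);
      add(std::string("b") + role, k, 1);
    }
  }
  add("W_fc1", c.L * k, c.fc_hidden); add("b_fc1", c.fc_hidden, 1);
  add("W_fc2", c.fc_hidden, c.m);     add("b_fc2", c.m, 1);
  return L;
}

template <typename eT>
struct PSetT {
  std::vector<PDef> defs;
  std::vector<Mat<eT>> M;
  Mat<eT>& at(const std::string& n) {
    for (size_t i = 0; i < defs.size(); ++i) if (defs[i].name == n) return M[i];
    Rcpp::stop("internal: parameter '" + n + "' absent in this configuration");
  }
};

template <typename eT>
static PSetT<eT> unpack(const vec& theta, const Cfg& c) {
  PSetT<eT> p; p.defs = make_layout(c);
  size_t off = 0;
  for (const auto& d : p.defs) {
    size_t sz = (size_t)d.nr * d.nc;
    if (off + sz > theta.n_elem) Rcpp::stop("parameter vector too short for configuration");
    p.M.emplace_back(conv_to<Mat<eT>>::from(reshape(theta.subvec(off, off + sz - 1), d.nr, d.nc)));
    off += sz;
  }
  if (off != theta.n_elem) Rcpp::stop("parameter vector length does not match configuration");
  return p;
}

template <typename eT>
static vec pack(const PSetT<eT>& p) {
  size_t total = 0;
  for (const auto& m : p.M) total += m.n_elem;
  vec out(total);
  size_t off = 0;
  for (const auto& m : p.M) {
    out.subvec(off, off + m.n_elem - 1) = conv_to<vec>::from(vectorise(m));
    off += m.n_elem;
  }
  return out;
}

template <typename eT>
static PSetT<eT> zeros_like(const PSetT<eT>& p) {
  PSetT<eT> g; g.defs = p.defs;
  for (const auto& m : p.M) g.M.emplace_back(size(m), fill::zeros);
  return g;
}

// ----------------------------------------------------- small building blocks

template <typename eT>
static Mat<eT> resample_mat(int n, int L) {
  if (n == L) return eye<Mat<eT>>(L, L);
  Mat<eT> M(L, n, fill::zeros);
  for (int s = 1; s <= L; ++s) {
    double a = (double)(s - 1) / L, b = (double)s / L;
    int j0 = (int)std::floor(a * n) + 1;
    int j1 = std::min(n, (int)std::ceil(b * n));
    for (int j = j0; j <= j1; ++j) {
      double lo = std::max(a, (double)(j - 1) / n);
      double hi = std::min(b, (double)j / n);
      if (hi > lo) M(s - 1, j - 1) = (eT)(hi - lo);
    }
    M.row(s - 1) /= (eT)(b - a);
  }
  return M;
}

template <typename MT>
static MT elu_f(const MT& x) {
  MT y = x;
  uvec id = find(x < 0);
  y.elem(id) = exp(x.elem(id)) - 1.0;
  return y;
}

// gradient factor d elu / dx from input x and output y (alpha = 1)
template <typename MT>
static MT elu_g(const MT& x, const MT& y) {
  MT g(size(x), fill::ones);
  uvec id = find(x < 0);
  g.elem(id) = y.elem(id) + 1.0;
  return g;
}

template <typename eT>
static Mat<eT> col_softmax(Mat<eT> S) {
  Row<eT> mx = max(S, 0);
  S.each_row() -= mx;
  S = exp(S);
  Row<eT> cs = sum(S, 0);
  S.each_row() /= cs;
  return S;
}

// Attention with the weight matrix held in column form (one column per
// query) so every softmax reduction runs over contiguous memory.
// Pc(j, i) = softmax_j(<Q_i, K_j> / sqrt(dk)); output O = Pc' * V.
template <typename eT>
static Mat<eT> attn_fwd(const Mat<eT>& Q, const Mat<eT>& K, const Mat<eT>& V,
                        double dk, Mat<eT>& Pc) {
  Pc = col_softmax<eT>(K * Q.t() / (eT)std::sqrt(dk));
  return Pc.t() * V;
}

template <typename eT>
static Mat<eT> attn_fwd(const Mat<eT>& Q, const Mat<eT>& K, const Mat<eT>& V,
                        double dk) {
  Mat<eT> Pc;
  return attn_fwd(Q, K, V, dk, Pc);
}

// uses the stored column-form weights; adds into dQ, dK, dV
template <typename eT>
static void attn_bwd(const Mat<eT>& Q, const Mat<eT>& K, const Mat<eT>& V,
                     double dk, const Mat<eT>& Pc, const Mat<eT>& dO,
                     Mat<eT>& dQ, Mat<eT>& dK, Mat<eT>& dV) {
  eT sc = (eT)(1.0 / std::sqrt(dk));
  dV += Pc * dO;
  Mat<eT> dPc = V * dO.t();              // dPc(j, i) = <V_j, dO_i>
  Row<eT> cdot = sum(dPc % Pc, 0);
  dPc.each_row() -= cdot;
  Mat<eT> dSc = (Pc % dPc) * sc;
  dQ += dSc.t() * K;
  dK += dSc * Q;
}

template <typename eT>
static Mat<eT> ln_fwd(const Mat<eT>& x, const Col<eT>& gain, const Col<eT>& shift,
                      Mat<eT>& xhat, Col<eT>& invstd) {
  Col<eT> mu = mean(x, 1);
  Mat<eT> xc = x.each_col() - mu;
  Col<eT> v = mean(xc % xc, 1);
  invstd = 1.0 / sqrt(v + (eT)LN_EPS);
  xhat = xc.each_col() % invstd;
  Mat<eT> y = xhat.each_row() % gain.t();
  y.each_row() += shift.t();
  return y;
}

template <typename eT>
static Mat<eT> ln_bwd(const Mat<eT>& dy, const Mat<eT>& xhat, const Col<eT>& invstd,
                      const Col<eT>& gain, Mat<eT>& dgain, Mat<eT>& dshift) {
  dgain += sum(dy % xhat, 0).t();
  dshift += sum(dy, 0).t();
  Mat<eT> dxhat = dy.each_row() % gain.t();
  Col<eT> m1 = mean(dxhat, 1);
  Col<eT> m2 = mean(dxhat % xhat, 1);
  Mat<eT> dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  return dx;
}

template <typename eT>
static void bn_fwd_train(const Mat<eT>& A, const Col<eT>& gamma, const Col<eT>& beta,
                         Col<eT>& run_mean, Col<eT>& run_var, bool update_state,
                         Mat<eT>& xhat, Col<eT>& invstd, Mat<eT>& out) {
  const double N = (double)A.n_cols;
  Col<eT> mu = mean(A, 1);
  Mat<eT> xc = A.each_col() - mu;
  Col<eT> v = mean(xc % xc, 1);
  invstd = 1.0 / sqrt(v + (eT)BN_EPS);
  xhat = xc.each_col() % invstd;
  out = xhat.each_col() % gamma;
  out.each_col() += beta;
  if (update_state) {
    eT ub = (eT)(N > 1 ? N / (N - 1.0) : 1.0);
    run_mean = (eT)(1 - BN_MOM) * run_mean + (eT)BN_MOM * mu;
    run_var  = (eT)(1 - BN_MOM) * run_var  + (eT)BN_MOM * (v * ub);
  }
}

template <typename eT>
static Mat<eT> bn_bwd(const Mat<eT>& dy, const Mat<eT>& xhat, const Col<eT>& invstd,
                      const Col<eT>& gamma, Mat<eT>& dgamma, Mat<eT>& dbeta) {
  dgamma += sum(dy % xhat, 1);
  dbeta += sum(dy, 1);
  Mat<eT> dxhat = dy.each_col() % gamma;
  Col<eT> m1 = mean(dxhat, 1);
  Col<eT> m2 = mean(dxhat % xhat, 1);
  Mat<eT> dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  return dx;
}

template <typename eT>
static Mat<eT> bn_fwd_eval(const Mat<eT>& A, const Col<eT>& gamma, const Col<eT>& beta,
                           const Col<eT>& rm, const Col<eT>& rv) {
  Col<eT> sc = gamma / sqrt(rv + (eT)BN_EPS);
  Mat<eT> out = A.each_col() - rm;
  out.each_col() %= sc;
  out.each_col() += beta;
  return out;
}

// ------------------------------------------------------------ convolutions
// Activation layout: one matrix per stage, k rows (feature maps), columns
// are the (plane, trial) cells; planes are stored column-major.

// conv1 / conv4 pattern: 1-d kernel along the second plane axis (time).
template <typename eT>
static void conv_time_fwd(const Mat<eT>& X, const Mat<eT>& W, int planeH, int kt,
                          Mat<eT>& col, Mat<eT>& A) {
  int c_in = X.n_rows;
  int Wout = X.n_cols / planeH - kt + 1;
  col.set_size(c_in * kt, planeH * Wout);
  for (int v = 0; v < kt; ++v)
    col.rows(v * c_in, (v + 1) * c_in - 1) = X.cols(v * planeH, v * planeH + planeH * Wout - 1);
  A = W.t() * col;
}

template <typename eT>
static void conv_time_bwd_input(const Mat<eT>& W, const Mat<eT>& dA, int planeH,
                                int kt, int c_in, int Win, Mat<eT>& dX) {
  Mat<eT> dcol = W * dA;
  dX.zeros(c_in, planeH * Win);
  int Wout = Win - kt + 1;
  for (int v = 0; v < kt; ++v)
    dX.cols(v * planeH, v * planeH + planeH * Wout - 1) += dcol.rows(v * c_in, (v + 1) * c_in - 1);
}

// conv2 / conv3 pattern: 1-d kernel along the first plane axis (electrodes).
template <typename eT>
static void conv_space_fwd(const Mat<eT>& X, const Mat<eT>& W, int planeH_in,
                           int kc, Mat<eT>& col, Mat<eT>& A) {
  int c_in = X.n_rows;
  int Wp = X.n_cols / planeH_in;
  int Hout = planeH_in - kc + 1;
  col.set_size(c_in * kc, Hout * Wp);
  for (int v = 0; v < kc; ++v)
    for (int j = 0; j < Wp; ++j)
      col.submat(v * c_in, j * Hout, (v + 1) * c_in - 1, (j + 1) * Hout - 1) =
        X.cols(j * planeH_in + v, j * planeH_in + v + Hout - 1);
  A = W.t() * col;
}

template <typename eT>
static void conv_space_bwd_input(const Mat<eT>& W, const Mat<eT>& dA, int planeH_in,
                                 int kc, int c_in, Mat<eT>& dX) {
  Mat<eT> dcol = W * dA;
  int Hout = planeH_in - kc + 1;
  int Wp = dA.n_cols / Hout;
  dX.zeros(c_in, planeH_in * Wp);
  for (int v = 0; v < kc; ++v)
    for (int j = 0; j < Wp; ++j)
      dX.cols(j * planeH_in + v, j * planeH_in + v + Hout - 1) +=
        dcol.submat(v * c_in, j * Hout, (v + 1) * c_in - 1, (j + 1) * Hout - 1);
}

template <typename eT>
static void pool_fwd(const Mat<eT>& X, int H2, int Hp, int Wp, Mat<eT>& P) {
  P.zeros(X.n_rows, Hp * Wp);
  for (int j = 0; j < Wp; ++j)
    for (int jj = 0; jj < 4; ++jj)
      for (int i = 0; i < Hp; ++i)
        for (int ii = 0; ii < 4; ++ii)
          P.col(i + j * Hp) += X.col((4 * i + ii) + (4 * j + jj) * H2);
  P /= (eT)16.0;
}

template <typename eT>
static void pool_bwd(const Mat<eT>& dP, int H2, int W1, int Hp, int Wp, Mat<eT>& dX) {
  dX.zeros(dP.n_rows, H2 * W1);
  Mat<eT> dP16 = dP / (eT)16.0;
  for (int j = 0; j < Wp; ++j)
    for (int jj = 0; jj < 4; ++jj)
      for (int i = 0; i < Hp; ++i)
        for (int ii = 0; ii < 4; ++ii)
          dX.col((4 * i + ii) + (4 * j + jj) * H2) += dP16.col(i + j * Hp);
}

// column-major plane (k x Hp*Wp) -> row-major position matrix (npos x k)
template <typename eT>
static Mat<eT> plane_to_positions(const Mat<eT>& P, int Hp, int Wp) {
  Mat<eT> F(Hp * Wp, P.n_rows);
  for (int i = 0; i < Hp; ++i)
    for (int j = 0; j < Wp; ++j)
      F.row(i * Wp + j) = P.col(i + j * Hp).t();
  return F;
}

template <typename eT>
static Mat<eT> positions_to_plane(const Mat<eT>& dF, int Hp, int Wp) {
  Mat<eT> dP(dF.n_cols, Hp * Wp);
  for (int i = 0; i < Hp; ++i)
    for (int j = 0; j < Wp; ++j)
      dP.col(i + j * Hp) = dF.row(i * Wp + j).t();
  return dP;
}

// ------------------------------------------------------------ batch caches

template <typename eT>
struct Cache {
  // LFEM (variant != no_lfem)
  std::vector<Mat<eT>> col_t1, col_t2, col_s1, col_s2;  // im2col buffers per trial
  Mat<eT> A2, A4;            // second-conv outputs, batch-stacked (k x B*H2*W1)
  Mat<eT> xh_t, xh_s;        // BN xhat
  Col<eT> is_t, is_s;        // BN invstd
  Mat<eT> bo_t, bo_s;        // BN output (ELU input)
  Mat<eT> eo_t, eo_s;        // ELU output (pool input)
  // no_lfem streams
  std::vector<Col<eT>> rs_t, rs_s;    // resampled raw streams (L x 1)
  // sequences
  std::vector<Mat<eT>> St, Ss;        // temporal / spatial sequences (L x k)
};

// forward one batch; if `grads` is non-null, also backprop into it.
// Returns total (summed) loss over the batch; fills `correct`.
template <typename eT>
static double run_batch(PSetT<eT>& P, const Cfg& c, const Cube<eT>& X,
                        const uvec& idx, const ivec& labels, bool train,
                        bool update_state, Col<eT>& state,
                        std::mt19937_64* rng, PSetT<eT>* grads,
                        int& correct, mat* logits_out) {
  const int B = idx.n_elem;
  const int k = c.k, L = c.L;
  Cache<eT> ca;
  Mat<eT> Mseq;          // resample matrix for sequences
  Mat<eT> Mraw;          // resample matrix for raw streams (no_lfem)
  const bool need_back = grads != nullptr;

  // ---------- front end: two feature sequences per trial ----------
  ca.St.resize(B); ca.Ss.resize(B);
  if (c.variant != 1) {
    Mseq = resample_mat<eT>(c.npos, L);
    const int Pt = c.H2 * c.W1;       // plane cells after second conv
    ca.col_t1.resize(B); ca.col_t2.resize(B); ca.col_s1.resize(B); ca.col_s2.resize(B);
    ca.A2.set_size(k, B * Pt); ca.A4.set_size(k, B * Pt);
    for (int b = 0; b < B; ++b) {
      Mat<eT> x = X.slice(idx(b));             // ch x t
      Mat<eT> xr = reshape(x, 1, c.ch * c.t);  // single input map over the (ch, t) plane
      Mat<eT> A1, A2, A3, A4;
      // temporal-first: time conv on (ch, t) plane, then space conv
      conv_time_fwd(xr, P.at("conv_t1_w"), c.ch, c.kt, ca.col_t1[b], A1);
      conv_space_fwd(A1, P.at("conv_t2_w"), c.ch, c.kc, ca.col_t2[b], A2);
      // spatial-first: space conv on (ch, t) plane, then time conv
      conv_space_fwd(xr, P.at("conv_s1_w"), c.ch, c.kc, ca.col_s1[b], A3);
      conv_time_fwd(A3, P.at("conv_s2_w"), c.H2, c.kt, ca.col_s2[b], A4);
      ca.A2.cols(b * Pt, (b + 1) * Pt - 1) = A2;
      ca.A4.cols(b * Pt, (b + 1) * Pt - 1) = A4;
    }
    Col<eT> rm_t = state.subvec(0, k - 1), rv_t = state.subvec(k, 2 * k - 1);
    Col<eT> rm_s = state.subvec(2 * k, 3 * k - 1), rv_s = state.subvec(3 * k, 4 * k - 1);
    if (train) {
      bn_fwd_train(ca.A2, Col<eT>(P.at("bn_t_gamma").col(0)), Col<eT>(P.at("bn_t_beta").col(0)),
                   rm_t, rv_t, update_state, ca.xh_t, ca.is_t, ca.bo_t);
      bn_fwd_train(ca.A4, Col<eT>(P.at("bn_s_gamma").col(0)), Col<eT>(P.at("bn_s_beta").col(0)),
                   rm_s, rv_s, update_state, ca.xh_s, ca.is_s, ca.bo_s);
      if (update_state) {
        state.subvec(0, k - 1) = rm_t; state.subvec(k, 2 * k - 1) = rv_t;
        state.subvec(2 * k, 3 * k - 1) = rm_s; state.subvec(3 * k, 4 * k - 1) = rv_s;
      }
    } else {
      ca.bo_t = bn_fwd_eval(ca.A2, Col<eT>(P.at("bn_t_gamma").col(0)),
                            Col<eT>(P.at("bn_t_beta").col(0)), rm_t, rv_t);
      ca.bo_s = bn_fwd_eval(ca.A4, Col<eT>(P.at("bn_s_gamma").col(0)),
                            Col<eT>(P.at("bn_s_beta").col(0)), rm_s, rv_s);
    }
    ca.eo_t = elu_f(ca.bo_t);
    ca.eo_s = elu_f(ca.bo_s);
    for (int b = 0; b < B; ++b) {
      Mat<eT> Pt_, Ps_;
      pool_fwd(Mat<eT>(ca.eo_t.cols(b * Pt, (b + 1) * Pt - 1)), c.H2, c.Hp, c.Wp, Pt_);
      pool_fwd(Mat<eT>(ca.eo_s.cols(b * Pt, (b + 1) * Pt - 1)), c.H2, c.Hp, c.Wp, Ps_);
      ca.St[b] = Mseq * plane_to_positions(Pt_, c.Hp, c.Wp);
      ca.Ss[b] = Mseq * plane_to_positions(Ps_, c.Hp, c.Wp);
    }
  } else {
    Mraw = resample_mat<eT>(c.ch * c.t, L);
    ca.rs_t.resize(B); ca.rs_s.resize(B);
    for (int b = 0; b < B; ++b) {
      Mat<eT> x = X.slice(idx(b));
      ca.rs_t[b] = Mraw * vectorise(x);
      ca.rs_s[b] = Mraw * vectorise(x.t());
      ca.St[b] = ca.rs_t[b] * P.at("proj_t_w");
      ca.St[b].each_row() += P.at("proj_t_b").col(0).t();
      ca.Ss[b] = ca.rs_s[b] * P.at("proj_s_w");
      ca.Ss[b].each_row() += P.at("proj_s_b").col(0).t();
    }
  }

  // ---------- per-trial attention stages ----------
  const int flat = L * k;
  const int hw = (c.variant != 2) ? k / c.h : 0;
  double total_loss = 0.0;
  correct = 0;

  // per-trial caches kept for the backward sweep (softmax weight matrices
  // are stored rather than recomputed; memory scales with batch size)
  std::vector<Mat<eT>> fusedv(B), Qts(B), Kts(B), Vts(B), Qst(B), Kst(B), Vst(B),
      Pts(B), Pst(B), ftsv(B), fstv(B), ln_xhv(B), gQ(B), gK(B), gV(B), gC(B);
  std::vector<Col<eT>> ln_isv(B);
  std::vector<Row<eT>> atwv(B);
  std::vector<std::vector<Mat<eT>>> Pgv(B);

  auto proj = [&](const Mat<eT>& S, const char* w, const char* bia) {
    Mat<eT> out = S * P.at(w);
    out.each_row() += P.at(bia).col(0).t();
    return out;
  };

  Mat<eT> Z(flat, B);
  for (int b = 0; b < B; ++b) {
    const Mat<eT>& St = ca.St[b];
    const Mat<eT>& Ss = ca.Ss[b];
    Mat<eT> fused;
    if (c.fusion == 0) {
      Qts[b] = proj(St, "Wq_ts", "bq_ts");
      Kts[b] = proj(Ss, "Wk_ts", "bk_ts");
      Vts[b] = proj(Ss, "Wv_ts", "bv_ts");
      Qst[b] = proj(Ss, "Wq_st", "bq_st");
      Kst[b] = proj(St, "Wk_st", "bk_st");
      Vst[b] = proj(St, "Wv_st", "bv_st");
      Mat<eT> fts, fst;
      if (need_back) {
        fts = attn_fwd(Qts[b], Kts[b], Vts[b], k, Pts[b]);
        fst = attn_fwd(Qst[b], Kst[b], Vst[b], k, Pst[b]);
      } else {
        fts = attn_fwd(Qts[b], Kts[b], Vts[b], k);
        fst = attn_fwd(Qst[b], Kst[b], Vst[b], k);
      }
      Mat<eT> pre = P.at("alpha")(0, 0) * fts + P.at("beta")(0, 0) * fst;
      fused = ln_fwd(pre, Col<eT>(P.at("ln_gain").col(0)),
                     Col<eT>(P.at("ln_shift").col(0)), ln_xhv[b], ln_isv[b]);
      if (need_back) { ftsv[b] = fts; fstv[b] = fst; }
    } else if (c.fusion == 1) {
      fused = St + Ss;
    } else if (c.fusion == 2) {
      fused = join_rows(St, Ss) * P.at("Wcat");
      fused.each_row() += P.at("bcat").col(0).t();
    } else {
      Col<eT> pooled = join_cols(mean(St, 0).t(), mean(Ss, 0).t());
      Row<eT> wl = pooled.t() * P.at("Wat") + P.at("bat").col(0).t();
      atwv[b] = col_softmax<eT>(wl.t()).t();
      fused = atwv[b](0) * St + atwv[b](1) * Ss;
    }

    if (c.variant != 2) {
      gQ[b] = proj(fused, "Wgq", "bgq");
      gK[b] = proj(fused, "Wgk", "bgk");
      gV[b] = proj(fused, "Wgv", "bgv");
      Mat<eT> C(L, k);
      Pgv[b].resize(c.h);
      for (int l = 0; l < c.h; ++l) {
        span cs(l * hw, (l + 1) * hw - 1);
        if (need_back)
          C.cols(cs) = attn_fwd(Mat<eT>(gQ[b].cols(cs)), Mat<eT>(gK[b].cols(cs)),
                                Mat<eT>(gV[b].cols(cs)), hw, Pgv[b][l]);
        else
          C.cols(cs) = attn_fwd(Mat<eT>(gQ[b].cols(cs)), Mat<eT>(gK[b].cols(cs)),
                                Mat<eT>(gV[b].cols(cs)), hw);
      }
      gC[b] = C;
      Mat<eT> fgb = C * P.at("Wgo");
      fgb.each_row() += P.at("bgo").col(0).t();
      Z.col(b) = vectorise(fgb);
    } else {
      Z.col(b) = vectorise(fused);
    }
    if (need_back) fusedv[b] = fused;
  }

  // ---------- classifier (batched) ----------
  const double keep = 1.0 - (train ? c.dropout : 0.0);
  Mat<eT> mask1, mask2;
  if (train && c.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    mask1.set_size(flat, B);
    mask2.set_size(c.fc_hidden, B);
    // masks drawn trial-by-trial: first-layer mask, then hidden-layer mask
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < flat; ++i) mask1(i, b) = (U(*rng) < keep) ? (eT)(1.0 / keep) : (eT)0;
      for (int i = 0; i < c.fc_hidden; ++i) mask2(i, b) = (U(*rng) < keep) ? (eT)(1.0 / keep) : (eT)0;
    }
  } else {
    mask1 = ones<Mat<eT>>(flat, B);
    mask2 = ones<Mat<eT>>(c.fc_hidden, B);
  }
  Mat<eT> Zd = Z % mask1;
  Mat<eT> H1 = P.at("W_fc1").t() * Zd;
  H1.each_col() += P.at("b_fc1").col(0);
  Mat<eT> H1a = elu_f(H1);
  Mat<eT> Ad = H1a % mask2;
  Mat<eT> logits = P.at("W_fc2").t() * Ad;
  logits.each_col() += P.at("b_fc2").col(0);
  if (logits_out) *logits_out = conv_to<mat>::from(logits);

  Mat<eT> probs(c.m, B);
  for (int b = 0; b < B; ++b) {
    Col<eT> l = logits.col(b);
    double mx = l.max();
    Col<eT> e = exp(l - (eT)mx);
    double Zs = accu(e);
    probs.col(b) = e / (eT)Zs;
    int y = labels(idx(b)) - 1;
    if (y < 0 || y >= c.m) Rcpp::stop("label out of range 1..m");
    total_loss += std::log(Zs) + mx - (double)l(y);
    if ((int)l.index_max() == y) ++correct;
  }
  if (!need_back) return total_loss;

  // =================== backward (mean-loss gradients) ===================
  PSetT<eT>& G = *grads;
  Mat<eT> dlog = probs;
  for (int b = 0; b < B; ++b) dlog(labels(idx(b)) - 1, b) -= (eT)1;
  dlog /= (eT)B;

  G.at("W_fc2") += Ad * dlog.t();
  G.at("b_fc2") += sum(dlog, 1);
  Mat<eT> dAd = P.at("W_fc2") * dlog;
  Mat<eT> dH1 = (dAd % mask2) % elu_g(H1, H1a);
  G.at("W_fc1") += Zd * dH1.t();
  G.at("b_fc1") += sum(dH1, 1);
  Mat<eT> dZ = (P.at("W_fc1") * dH1) % mask1;

  std::vector<Mat<eT>> dSt(B), dSs(B);
  for (int b = 0; b < B; ++b) {
    const Mat<eT>& St = ca.St[b];
    const Mat<eT>& Ss = ca.Ss[b];
    Mat<eT> dtop = reshape(Mat<eT>(dZ.col(b)), L, k);

    Mat<eT> dfused;
    if (c.variant != 2) {
      G.at("Wgo") += gC[b].t() * dtop;
      G.at("bgo") += sum(dtop, 0).t();
      Mat<eT> dC = dtop * P.at("Wgo").t();
      Mat<eT> dQ(L, k, fill::zeros), dK(L, k, fill::zeros), dV(L, k, fill::zeros);
      for (int l = 0; l < c.h; ++l) {
        span cs(l * hw, (l + 1) * hw - 1);
        Mat<eT> dq(L, hw, fill::zeros), dk_(L, hw, fill::zeros), dv(L, hw, fill::zeros);
        attn_bwd(Mat<eT>(gQ[b].cols(cs)), Mat<eT>(gK[b].cols(cs)),
                 Mat<eT>(gV[b].cols(cs)), hw, Pgv[b][l],
                 Mat<eT>(dC.cols(cs)), dq, dk_, dv);
        dQ.cols(cs) = dq; dK.cols(cs) = dk_; dV.cols(cs) = dv;
      }
      G.at("Wgq") += fusedv[b].t() * dQ;  G.at("bgq") += sum(dQ, 0).t();
      G.at("Wgk") += fusedv[b].t() * dK;  G.at("bgk") += sum(dK, 0).t();
      G.at("Wgv") += fusedv[b].t() * dV;  G.at("bgv") += sum(dV, 0).t();
      dfused = dQ * P.at("Wgq").t() + dK * P.at("Wgk").t() + dV * P.at("Wgv").t();
    } else {
      dfused = dtop;
    }

    if (c.fusion == 0) {
      Mat<eT> dpre = ln_bwd(dfused, ln_xhv[b], ln_isv[b],
                            Col<eT>(P.at("ln_gain").col(0)),
                            G.at("ln_gain"), G.at("ln_shift"));
      G.at("alpha")(0, 0) += accu(dpre % ftsv[b]);
      G.at("beta")(0, 0)  += accu(dpre % fstv[b]);
      Mat<eT> dfts = P.at("alpha")(0, 0) * dpre, dfst = P.at("beta")(0, 0) * dpre;
      Mat<eT> dQ(L, k, fill::zeros), dK(L, k, fill::zeros), dV(L, k, fill::zeros);
      attn_bwd(Qts[b], Kts[b], Vts[b], k, Pts[b], dfts, dQ, dK, dV);
      G.at("Wq_ts") += St.t() * dQ;  G.at("bq_ts") += sum(dQ, 0).t();
      G.at("Wk_ts") += Ss.t() * dK;  G.at("bk_ts") += sum(dK, 0).t();
      G.at("Wv_ts") += Ss.t() * dV;  G.at("bv_ts") += sum(dV, 0).t();
      dSt[b] = dQ * P.at("Wq_ts").t();
      dSs[b] = dK * P.at("Wk_ts").t() + dV * P.at("Wv_ts").t();
      dQ.zeros(); dK.zeros(); dV.zeros();
      attn_bwd(Qst[b], Kst[b], Vst[b], k, Pst[b], dfst, dQ, dK, dV);
      G.at("Wq_st") += Ss.t() * dQ;  G.at("bq_st") += sum(dQ, 0).t();
      G.at("Wk_st") += St.t() * dK;  G.at("bk_st") += sum(dK, 0).t();
      G.at("Wv_st") += St.t() * dV;  G.at("bv_st") += sum(dV, 0).t();
      dSs[b] += dQ * P.at("Wq_st").t();
      dSt[b] += dK * P.at("Wk_st").t() + dV * P.at("Wv_st").t();
    } else if (c.fusion == 1) {
      dSt[b] = dfused; dSs[b] = dfused;
    } else if (c.fusion == 2) {
      G.at("Wcat") += join_rows(St, Ss).t() * dfused;
      G.at("bcat") += sum(dfused, 0).t();
      Mat<eT> dcat = dfused * P.at("Wcat").t();
      dSt[b] = dcat.cols(0, k - 1);
      dSs[b] = dcat.cols(k, 2 * k - 1);
    } else {
      eT w0 = atwv[b](0), w1 = atwv[b](1);
      dSt[b] = w0 * dfused;
      dSs[b] = w1 * dfused;
      Col<eT> dw(2);
      dw(0) = accu(dfused % St);
      dw(1) = accu(dfused % Ss);
      Col<eT> w = {w0, w1};
      Col<eT> dl = w % (dw - (eT)dot(dw, w));
      Col<eT> pooled = join_cols(mean(St, 0).t(), mean(Ss, 0).t());
      G.at("Wat") += pooled * dl.t();
      G.at("bat") += dl;
      Col<eT> dpooled = P.at("Wat") * dl;
      dSt[b].each_row() += dpooled.subvec(0, k - 1).t() / (eT)L;
      dSs[b].each_row() += dpooled.subvec(k, 2 * k - 1).t() / (eT)L;
    }
  }

  if (c.variant != 1) {
    const int Pt = c.H2 * c.W1;
    Mat<eT> dEo_t(k, B * Pt), dEo_s(k, B * Pt);
    for (int b = 0; b < B; ++b) {
      Mat<eT> dPt = positions_to_plane(Mat<eT>(Mseq.t() * dSt[b]), c.Hp, c.Wp);
      Mat<eT> dPs = positions_to_plane(Mat<eT>(Mseq.t() * dSs[b]), c.Hp, c.Wp);
      Mat<eT> dxt, dxs;
      pool_bwd(dPt, c.H2, c.W1, c.Hp, c.Wp, dxt);
      pool_bwd(dPs, c.H2, c.W1, c.Hp, c.Wp, dxs);
      dEo_t.cols(b * Pt, (b + 1) * Pt - 1) = dxt;
      dEo_s.cols(b * Pt, (b + 1) * Pt - 1) = dxs;
    }
    Mat<eT> dBo_t = dEo_t % elu_g(ca.bo_t, ca.eo_t);
    Mat<eT> dBo_s = dEo_s % elu_g(ca.bo_s, ca.eo_s);
    Mat<eT> dA2 = bn_bwd(dBo_t, ca.xh_t, ca.is_t, Col<eT>(P.at("bn_t_gamma").col(0)),
                         G.at("bn_t_gamma"), G.at("bn_t_beta"));
    Mat<eT> dA4 = bn_bwd(dBo_s, ca.xh_s, ca.is_s, Col<eT>(P.at("bn_s_gamma").col(0)),
                         G.at("bn_s_gamma"), G.at("bn_s_beta"));
    for (int b = 0; b < B; ++b) {
      Mat<eT> dA2b = dA2.cols(b * Pt, (b + 1) * Pt - 1);
      Mat<eT> dA4b = dA4.cols(b * Pt, (b + 1) * Pt - 1);
      G.at("conv_t2_w") += ca.col_t2[b] * dA2b.t();
      Mat<eT> dA1;
      conv_space_bwd_input(P.at("conv_t2_w"), dA2b, c.ch, c.kc, k, dA1);
      G.at("conv_t1_w") += ca.col_t1[b] * dA1.t();
      G.at("conv_s2_w") += ca.col_s2[b] * dA4b.t();
      Mat<eT> dA3;
      conv_time_bwd_input(P.at("conv_s2_w"), dA4b, c.H2, c.kt, k, c.t, dA3);
      G.at("conv_s1_w") += ca.col_s1[b] * dA3.t();
    }
  } else {
    for (int b = 0; b < B; ++b) {
      G.at("proj_t_w") += ca.rs_t[b].t() * dSt[b];
      G.at("proj_t_b") += sum(dSt[b], 0).t();
      G.at("proj_s_w") += ca.rs_s[b].t() * dSs[b];
      G.at("proj_s_b") += sum(dSs[b], 0).t();
    }
  }

  return total_loss;
}

// -------------------------------------------------------------- interfaces

// [[Rcpp::export]]
Rcpp::List cpp_train(arma::vec theta, arma::vec state, Rcpp::List cfg_list,
                     arma::cube X, arma::ivec labels, int epochs,
                     double lr, int lr_step, double lr_gamma,
                     int batch_size, int seed) {
  typedef float eT;
  Cfg c = parse_cfg(cfg_list);
  const int N = X.n_slices;
  if ((int)labels.n_elem != N) Rcpp::stop("label count does not match trial count");
  if (N < 1) Rcpp::stop("empty training set");
  Cube<eT> Xf = conv_to<Cube<eT>>::from(X);
  PSetT<eT> P = unpack<eT>(theta, c);
  PSetT<eT> G = zeros_like(P);
  Col<eT> st = conv_to<Col<eT>>::from(state);
  vec th = theta;
  vec am(th.n_elem, fill::zeros), av(th.n_elem, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::mt19937_64 rng((uint64_t)seed);
  mat history(epochs, 3);
  std::vector<uword> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    double cur_lr = lr * std::pow(lr_gamma, ep / lr_step);
    std::shuffle(ord.begin(), ord.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      int stop = std::min(N, start + batch_size);
      uvec idx(stop - start);
      for (int i = start; i < stop; ++i) idx(i - start) = ord[i];
      for (auto& g : G.M) g.zeros();
      int correct = 0;
      double l = run_batch<eT>(P, c, Xf, idx, labels, true, true, st, &rng, &G,
                               correct, nullptr);
      ep_loss += l;
      ep_correct += correct;
      // Adam step in double on the flat parameter vector
      vec g = pack(G);
      ++step;
      am = b1 * am + (1 - b1) * g;
      av = b2 * av + (1 - b2) * (g % g);
      vec mhat = am / (1 - std::pow(b1, (double)step));
      vec vhat = av / (1 - std::pow(b2, (double)step));
      th -= cur_lr * mhat / (sqrt(vhat) + eps);
      P = unpack<eT>(th, c);
    }
    history(ep, 0) = ep_loss / N;
    history(ep, 1) = (double)ep_correct / N;
    history(ep, 2) = cur_lr;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("theta") = th,
                            Rcpp::Named("state") = conv_to<vec>::from(st),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::mat cpp_predict(arma::vec theta, arma::vec state, Rcpp::List cfg_list,
                      arma::cube X) {
  Cfg c = parse_cfg(cfg_list);
  PSetT<double> P = unpack<double>(theta, c);
  vec st = state;
  const int N = X.n_slices;
  mat out(N, c.m);
  const int chunk = 64;
  for (int start = 0; start < N; start += chunk) {
    int stop = std::min(N, start + chunk);
    uvec idx(stop - start);
    for (int i = start; i < stop; ++i) idx(i - start) = i;
    ivec fake(N, fill::ones);
    int correct = 0;
    mat logits;
    run_batch<double>(P, c, X, idx, fake, false, false, st, nullptr, nullptr,
                      correct, &logits);
    out.rows(start, stop - 1) = logits.t();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(arma::vec theta, arma::vec state, Rcpp::List cfg_list,
                         arma::cube X, arma::ivec labels, int seed) {
  Cfg c = parse_cfg(cfg_list);
  PSetT<double> P = unpack<double>(theta, c);
  PSetT<double> G = zeros_like(P);
  vec st = state;
  uvec idx(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) idx(i) = i;
  std::mt19937_64 rng((uint64_t)seed);
  int correct = 0;
  double l = run_batch<double>(P, c, X, idx, labels, true, false, st, &rng, &G,
                               correct, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = l / (double)X.n_slices,
                            Rcpp::Named("grad") = pack(G),
                            Rcpp::Named("correct") = correct);
}
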