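// Attention-GRU sequence classifier: batched forward pass, analytic
// backpropagation and masked multitask binary cross-entropy loss.
//
// Architecture (per input, a D x T feature matrix presented as T column
// steps): learned elementwise normalization of each input column, a 2-layer
// GRU, soft attention over the deepest layer's hidden states scored by
//   score(l, h) = K . tanh(A . prelu(B . n([l, h])))
// (l = last deepest hidden state), a context vector (attention-weighted sum
// of deepest hidden states), and a 2-layer feed-forward classifier on
// [l, context] with a penultimate embedding and O sigmoid outputs.
//
// Implementation notes: all per-step quantities are stored stacked
// step-major (row t*N + i for sample i at step t), so every input-side
// projection and the whole attention scorer run as single large GEMMs; only
// the recurrent half of each GRU layer iterates over time. Parameters live
// in one flat vector; cpp_param_layout() documents the packing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Dims {
  int D, H, T, Aq, C, O;
  double eps;
};

static Dims make_dims(const Rcpp::IntegerVector &d, double eps) {
  Dims dm;
  dm.D = d[0]; dm.H = d[1]; dm.T = d[2];
  dm.Aq = d[3]; dm.C = d[4]; dm.O = d[5];
  dm.eps = eps;
  return dm;
}

// Parameter views into a flat vector (no copies; writable for gradients).
struct Params {
  vec mu_in, sg_in, a_in, b_in;
  mat W1, U1; vec bw1, bu1;       // layer-1 GRU, gate order r,z,n stacked
  mat W2, U2; vec bw2, bu2;       // layer-2 GRU
  vec mu_at, sg_at, a_at, b_at;   // normalization inside the attention net
  mat B; vec slope;               // slope: length-1 prelu parameter
  mat A; vec K;
  mat Wc1; vec bc1; mat Wc2; vec bc2;
};

static int n_params(const Dims &d) {
  int H3 = 3 * d.H, H2 = 2 * d.H;
  return 4 * d.D
    + H3 * d.D + H3 * d.H + 2 * H3
    + H3 * d.H + H3 * d.H + 2 * H3
    + 4 * H2
    + d.Aq * H2 + 1 + d.Aq * d.Aq + d.Aq
    + d.C * H2 + d.C + d.O * d.C + d.O;
}

static Params unpack(double *p, const Dims &d) {
  Params P;
  int H3 = 3 * d.H, H2 = 2 * d.H;
  double *q = p;
  auto v = [&](int n) { vec out(q, n, false, true); q += n; return out; };
  auto m = [&](int r, int c) { mat out(q, r, c, false, true); q += r * c; return out; };
  P.mu_in = v(d.D); P.sg_in = v(d.D); P.a_in = v(d.D); P.b_in = v(d.D);
  P.W1 = m(H3, d.D); P.U1 = m(H3, d.H); P.bw1 = v(H3); P.bu1 = v(H3);
  P.W2 = m(H3, d.H); P.U2 = m(H3, d.H); P.bw2 = v(H3); P.bu2 = v(H3);
  P.mu_at = v(H2); P.sg_at = v(H2); P.a_at = v(H2); P.b_at = v(H2);
  P.B = m(d.Aq, H2); P.slope = v(1); P.A = m(d.Aq, d.Aq); P.K = v(d.Aq);
  P.Wc1 = m(d.C, H2); P.bc1 = v(d.C); P.Wc2 = m(d.O, d.C); P.bc2 = v(d.O);
  return P;
}

static mat sigm(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// a * (x - mu)/(sg + eps) + b on rows of a stacked matrix; xc keeps the
// centred/scaled term for backprop
static void norm_fwd(const mat &x, const vec &mu, const vec &sg,
                     const vec &a, const vec &b, double eps,
                     mat &xc, mat &out) {
  xc = x;
  xc.each_row() -= mu.t();
  xc.each_row() /= (sg.t() + eps);
  out = xc;
  out.each_row() %= a.t();
  out.each_row() += b.t();
}

// stored intermediates, all stacked step-major (NT = N*T rows)
struct Tape {
  mat XF, XCin, Xn;                  // NT x D
  mat R1, Z1, N1, HU1, H1;           // NT x H
  mat R2, Z2, N2, HU2, H2;
  mat XCat, Uat, Gat, Pat, TAat;     // NT x 2H / NT x Aq
  mat S, Wt;                         // N x T
  mat l, context, f, pen_pre, pen, logits;
};

// recurrent half of one GRU layer; PW = stacked input projections + bias
static void gru_recur(const mat &PW, const mat &U, const vec &bu,
                      int N, int T, int H,
                      mat &R, mat &Z, mat &Nn, mat &HU, mat &Hs) {
  R.set_size(N * T, H); Z.set_size(N * T, H);
  Nn.set_size(N * T, H); HU.set_size(N * T, H); Hs.set_size(N * T, H);
  mat h(N, H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    span rs(t * N, (t + 1) * N - 1);
    mat pu = h * U.t(); pu.each_row() += bu.t();
    mat r = sigm(PW(rs, span(0, H - 1)) + pu.cols(0, H - 1));
    mat z = sigm(PW(rs, span(H, 2 * H - 1)) + pu.cols(H, 2 * H - 1));
    mat hun = pu.cols(2 * H, 3 * H - 1);
    mat n = tanh(PW(rs, span(2 * H, 3 * H - 1)) + r % hun);
    h = (1.0 - z) % n + z % h;
    R.rows(rs) = r; Z.rows(rs) = z; Nn.rows(rs) = n;
    HU.rows(rs) = hun; Hs.rows(rs) = h;
  }
}

static void forward_pass(const Params &P, const Dims &d, const cube &X,
                         Tape &tp) {
  int N = X.n_rows, T = d.T, H = d.H, H2 = 2 * d.H;
  int NT = N * T;

  tp.XF.set_size(NT, d.D);
  for (int t = 0; t < T; ++t) tp.XF.rows(t * N, (t + 1) * N - 1) = X.slice(t);
  norm_fwd(tp.XF, P.mu_in, P.sg_in, P.a_in, P.b_in, d.eps, tp.XCin, tp.Xn);

  mat PW1 = tp.Xn * P.W1.t(); PW1.each_row() += P.bw1.t();
  gru_recur(PW1, P.U1, P.bu1, N, T, H, tp.R1, tp.Z1, tp.N1, tp.HU1, tp.H1);
  mat PW2 = tp.H1 * P.W2.t(); PW2.each_row() += P.bw2.t();
  gru_recur(PW2, P.U2, P.bu2, N, T, H, tp.R2, tp.Z2, tp.N2, tp.HU2, tp.H2);

  tp.l = tp.H2.rows((T - 1) * N, NT - 1);

  // attention scorer, fully stacked
  mat CF(NT, H2);
  for (int t = 0; t < T; ++t) {
    span rs(t * N, (t + 1) * N - 1);
    CF(rs, span(0, H - 1)) = tp.l;
    CF(rs, span(H, H2 - 1)) = tp.H2.rows(rs);
  }
  norm_fwd(CF, P.mu_at, P.sg_at, P.a_at, P.b_at, d.eps, tp.XCat, tp.Uat);
  tp.Gat = tp.Uat * P.B.t();
  double sl = P.slope(0);
  mat pos = conv_to<mat>::from(tp.Gat > 0);
  tp.Pat = tp.Gat % pos + sl * (tp.Gat % (1.0 - pos));
  tp.TAat = tanh(tp.Pat * P.A.t());
  vec sv = tp.TAat * P.K;
  tp.S.set_size(N, T);
  for (int t = 0; t < T; ++t) tp.S.col(t) = sv.subvec(t * N, (t + 1) * N - 1);

  vec mx = max(tp.S, 1);
  mat e = exp(tp.S.each_col() - mx);
  tp.Wt = e.each_col() / sum(e, 1);

  tp.context.zeros(N, H);
  for (int t = 0; t < T; ++t)
    tp.context += tp.H2.rows(t * N, (t + 1) * N - 1).eval().each_col()
      % tp.Wt.col(t);

  tp.f = join_rows(tp.l, tp.context);
  tp.pen_pre = tp.f * P.Wc1.t(); tp.pen_pre.each_row() += P.bc1.t();
  tp.pen = tp.pen_pre % conv_to<mat>::from(tp.pen_pre > 0);
  tp.logits = tp.pen * P.Wc2.t(); tp.logits.each_row() += P.bc2.t();
}

// [[Rcpp::export]]
int cpp_n_params(Rcpp::IntegerVector dims) {
  return n_params(make_dims(dims, 1e-7));
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_param_layout(Rcpp::IntegerVector dims) {
  Dims d = make_dims(dims, 1e-7);
  int H3 = 3 * d.H, H2 = 2 * d.H;
  std::vector<std::string> nm;
  std::vector<int> nr, nc, off;
  int pos = 1;
  auto add = [&](const std::string &s, int r, int c) {
    nm.push_back(s); nr.push_back(r); nc.push_back(c); off.push_back(pos);
    pos += r * c;
  };
  add("mu_in", d.D, 1); add("sg_in", d.D, 1); add("a_in", d.D, 1); add("b_in", d.D, 1);
  add("W1", H3, d.D); add("U1", H3, d.H); add("bw1", H3, 1); add("bu1", H3, 1);
  add("W2", H3, d.H); add("U2", H3, d.H); add("bw2", H3, 1); add("bu2", H3, 1);
  add("mu_at", H2, 1); add("sg_at", H2, 1); add("a_at", H2, 1); add("b_at", H2, 1);
  add("B", d.Aq, H2); add("slope", 1, 1); add("A", d.Aq, d.Aq); add("K", d.Aq, 1);
  add("Wc1", d.C, H2); add("bc1", d.C, 1); add("Wc2", d.O, d.C); add("bc2", d.O, 1);
  return Rcpp::DataFrame::create(Rcpp::Named("name") = nm,
                                 Rcpp::Named("offset") = off,
                                 Rcpp::Named("nrow") = nr,
                                 Rcpp::Named("ncol") = nc);
}

static void check_input(const vec &par, const Dims &d, const cube &X) {
  if ((int)par.n_elem != n_params(d))
    Rcpp::stop("parameter vector has wrong length");
  if ((int)X.n_cols != d.D || (int)X.n_slices != d.T)
    Rcpp::stop("input array must be N x %d x %d", d.D, d.T);
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(arma::vec par, Rcpp::IntegerVector dims, double eps,
                       arma::cube X) {
  Dims d = make_dims(dims, eps);
  check_input(par, d, X);
  Params P = unpack(par.memptr(), d);
  static Tape tp;   // reused across calls to avoid reallocation
  forward_pass(P, d, X, tp);
  return Rcpp::List::create(
    Rcpp::Named("logits") = tp.logits,
    Rcpp::Named("probs") = sigm(tp.logits),
    Rcpp::Named("attention") = tp.Wt,
    Rcpp::Named("penultimate") = tp.pen,
    Rcpp::Named("context") = tp.context,
    Rcpp::Named("l") = tp.l);
}

// per-sample, per-outcome binary cross-entropy (no reduction)
// [[Rcpp::export]]
arma::mat cpp_bce(arma::vec par, Rcpp::IntegerVector dims, double eps,
                  arma::cube X, arma::mat Y) {
  Dims d = make_dims(dims, eps);
  check_input(par, d, X);
  Params P = unpack(par.memptr(), d);
  static Tape tp;
  forward_pass(P, d, X, tp);
  const mat &x = tp.logits;
  return max(x, zeros(size(x))) - x % Y + log1p(exp(-abs(x)));
}

// recurrent half of one GRU layer, backward; fills stacked gate gradients
// and returns nothing (dW/dU/db are assembled by the caller as big GEMMs)
static void gru_recur_bwd(const mat &R, const mat &Z, const mat &Nn,
                          const mat &HU, const mat &Hs, const mat &U,
                          const mat &dH_add, int N, int T, int H,
                          mat &dGW, mat &dGU) {
  dGW.set_size(N * T, 3 * H); dGU.set_size(N * T, 3 * H);
  mat carry(N, H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    span rs(t * N, (t + 1) * N - 1);
    mat dh = dH_add.rows(rs) + carry;
    mat h_prev = (t == 0) ? mat(N, H, fill::zeros)
                          : mat(Hs.rows((t - 1) * N, t * N - 1));
    mat r = R.rows(rs), z = Z.rows(rs), n = Nn.rows(rs), hun = HU.rows(rs);
    mat dz_gate = dh % (h_prev - n);
    mat dn_pre = (dh % (1.0 - z)) % (1.0 - n % n);
    mat dhun = dn_pre % r;
    mat dz_pre = dz_gate % (z % (1.0 - z));
    mat dr_pre = (dn_pre % hun) % (r % (1.0 - r));
    dGW(rs, span(0, H - 1)) = dr_pre;
    dGW(rs, span(H, 2 * H - 1)) = dz_pre;
    dGW(rs, span(2 * H, 3 * H - 1)) = dn_pre;
    dGU(rs, span(0, H - 1)) = dr_pre;
    dGU(rs, span(H, 2 * H - 1)) = dz_pre;
    dGU(rs, span(2 * H, 3 * H - 1)) = dhun;
    carry = dh % z + dGU.rows(rs) * U;
  }
}

// stacked h_{t-1} matrix (zeros for t = 0)
static mat shift_prev(const mat &Hs, int N, int T, int H) {
  mat out(N * T, H, fill::zeros);
  if (T > 1) out.rows(N, N * T - 1) = Hs.rows(0, N * (T - 1) - 1);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(arma::vec par, Rcpp::IntegerVector dims, double eps,
                         arma::cube X, arma::mat Y, arma::mat M) {
  Dims d = make_dims(dims, eps);
  check_input(par, d, X);
  int N = X.n_rows, T = d.T, H = d.H, H2 = 2 * d.H, NT = N * T;
  Params P = unpack(par.memptr(), d);
  static Tape tp;
  forward_pass(P, d, X, tp);

  // masked multitask BCE: per-sample mean over unmasked outcomes, then
  // mean over the batch
  vec rs_mask = sum(M, 1);
  if (any(rs_mask == 0)) Rcpp::stop("a sample has an all-zero loss mask");
  mat wgt = M.each_col() / rs_mask;
  wgt /= (double)N;
  const mat &x = tp.logits;
  mat bce = max(x, zeros(size(x))) - x % Y + log1p(exp(-abs(x)));
  double loss = accu(wgt % bce);

  vec gr(par.n_elem, fill::zeros);
  Params G = unpack(gr.memptr(), d);

  // classifier backward
  mat dlogits = wgt % (sigm(x) - Y);
  G.Wc2 += dlogits.t() * tp.pen;
  G.bc2 += sum(dlogits, 0).t();
  mat dpen_pre = (dlogits * P.Wc2) % conv_to<mat>::from(tp.pen_pre > 0);
  G.Wc1 += dpen_pre.t() * tp.f;
  G.bc1 += sum(dpen_pre, 0).t();
  mat df = dpen_pre * P.Wc1;
  mat dl = df.cols(0, H - 1);
  mat dcontext = df.cols(H, H2 - 1);

  // context backward: per-step hidden additions + softmax-weight grads
  mat dH2(NT, H, fill::zeros);
  mat dWt(N, T);
  for (int t = 0; t < T; ++t) {
    span rs(t * N, (t + 1) * N - 1);
    dH2.rows(rs) += dcontext.each_col() % tp.Wt.col(t);
    dWt.col(t) = sum(dcontext % tp.H2.rows(rs), 1);
  }
  vec dot = sum(dWt % tp.Wt, 1);
  mat dS = tp.Wt % (dWt.each_col() - dot);

  // attention backward, fully stacked
  vec dsv(NT);
  for (int t = 0; t < T; ++t)
    dsv.subvec(t * N, (t + 1) * N - 1) = dS.col(t);
  G.K += tp.TAat.t() * dsv;
  mat dTA = dsv * P.K.t();
  mat dR2a = dTA % (1.0 - tp.TAat % tp.TAat);
  G.A += dR2a.t() * tp.Pat;
  mat dP = dR2a * P.A;
  double sl = P.slope(0);
  mat posg = conv_to<mat>::from(tp.Gat > 0);
  G.slope(0) += accu(dP % tp.Gat % (1.0 - posg));
  mat dG = dP % (posg + sl * (1.0 - posg));
  G.B += dG.t() * tp.Uat;
  mat dU = dG * P.B;
  vec sxc_at = sum(dU % tp.XCat, 0).t();
  vec inv_at = P.a_at / (P.sg_at + d.eps);
  G.a_at += sxc_at;
  G.b_at += sum(dU, 0).t();
  mat dC = dU;
  dC.each_row() %= inv_at.t();
  G.mu_at -= sum(dC, 0).t();
  G.sg_at -= sxc_at % inv_at;
  for (int t = 0; t < T; ++t) {
    span rs(t * N, (t + 1) * N - 1);
    dl += dC(rs, span(0, H - 1));
    dH2.rows(rs) += dC(rs, span(H, H2 - 1));
  }
  // l is the last hidden state of layer 2
  dH2.rows((T - 1) * N, NT - 1) += dl;

  mat dGW2, dGU2;
  gru_recur_bwd(tp.R2, tp.Z2, tp.N2, tp.HU2, tp.H2, P.U2, dH2, N, T, H,
                dGW2, dGU2);
  G.W2 += dGW2.t() * tp.H1;
  G.bw2 += sum(dGW2, 0).t();
  mat Hp2 = shift_prev(tp.H2, N, T, H);
  G.U2 += dGU2.t() * Hp2;
  G.bu2 += sum(dGU2, 0).t();
  mat dH1 = dGW2 * P.W2;

  mat dGW1, dGU1;
  gru_recur_bwd(tp.R1, tp.Z1, tp.N1, tp.HU1, tp.H1, P.U1, dH1, N, T, H,
                dGW1, dGU1);
  G.W1 += dGW1.t() * tp.Xn;
  G.bw1 += sum(dGW1, 0).t();
  mat Hp1 = shift_prev(tp.H1, N, T, H);
  G.U1 += dGU1.t() * Hp1;
  G.bu1 += sum(dGU1, 0).t();
  mat dXn = dGW1 * P.W1;

  // input normalization backward (X itself needs no gradient)
  vec sxc_in = sum(dXn % tp.XCin, 0).t();
  vec inv_in = P.a_in / (P.sg_in + d.eps);
  G.a_in += sxc_in;
  G.b_in += sum(dXn, 0).t();
  dXn.each_row() %= inv_in.t();
  G.mu_in -= sum(dXn, 0).t();
  G.sg_in -= sxc_in % inv_in;

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = gr);
}

// [[Rcpp::export]]
double cpp_loss(arma::vec par, Rcpp::IntegerVector dims, double eps,
                arma::cube X, arma::mat Y, arma::mat M) {
  Dims d = make_dims(dims, eps);
  check_input(par, d, X);
  Params P = unpack(par.memptr(), d);
  static Tape tp;
  forward_pass(P, d, X, tp);
  vec rs = sum(M, 1);
  if (any(rs == 0)) Rcpp::stop("a sample has an all-zero loss mask");
  mat wgt = M.each_col() / rs;
  wgt /= (double)X.n_rows;
  const mat &x = tp.logits;
  mat bce = max(x, zeros(size(x))) - x % Y + log1p(exp(-abs(x)));
  return accu(wgt % bce);
}
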