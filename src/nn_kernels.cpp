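// Compiled kernels for the two sequence layers that dominate training
// time: the kernel-8 stride-1 'same' convolution and the LSTM. Tensors
// arrive flattened as (B*L, C) column-major matrices (R array layout
// with batch fastest). Activation codes: 0 linear, 1 LeakyReLU(0.2),
// 2 sigmoid, 3 tanh.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat act_f(const mat& x, int act) {
  switch (act) {
    case 1: return x % (conv_to<mat>::from(x > 0) * 0.8 + 0.2);
    case 2: return 1.0 / (1.0 + exp(-x));
    case 3: return tanh(x);
    default: return x;
  }
}

// derivative given pre-activation x and post-activation y
static mat act_d(const mat& x, const mat& y, int act) {
  switch (act) {
    case 1: return conv_to<mat>::from(x > 0) * 0.8 + 0.2;
    case 2: return y % (1.0 - y);
    case 3: return 1.0 - y % y;
    default: return ones<mat>(x.n_rows, x.n_cols);
  }
}

// im2col for kernel 8, stride 1, 'same' padding (3 left, 4 right)
static mat im2col8(const mat& Xf, int B, int L) {
  const int C = Xf.n_cols;
  mat Xcol(B * L, 8 * C, fill::zeros);
  for (int j = 0; j < 8; ++j) {
    const int off = j - 3;  // source time offset
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t0 >= t1) continue;
    Xcol.submat(t0 * B, j * C, t1 * B - 1, (j + 1) * C - 1) =
      Xf.rows((t0 + off) * B, (t1 + off) * B - 1);
  }
  return Xcol;
}

// [[Rcpp::export(name = ".conv8_fwd")]]
Rcpp::List conv8_fwd(const arma::mat& Xf, int B, int L, const arma::mat& W,
                     const arma::rowvec& b, int act) {
  mat Xcol = im2col8(Xf, B, L);
  mat z = Xcol * W;
  z.each_row() += b;
  mat y = act_f(z, act);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("z") = z,
                            Rcpp::Named("Xcol") = Xcol);
}

// [[Rcpp::export(name = ".conv8_bwd")]]
Rcpp::List conv8_bwd(const arma::mat& dY, const arma::mat& z, const arma::mat& y,
                     const arma::mat& Xcol, const arma::mat& W, int B, int L,
                     int act) {
  const int C = W.n_rows / 8;
  mat dz = dY % act_d(z, y, act);
  mat dW = Xcol.t() * dz;
  rowvec db = sum(dz, 0);
  mat dXcol = dz * W.t();
  mat dXf(B * L, C, fill::zeros);
  for (int j = 0; j < 8; ++j) {
    const int off = j - 3;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t0 >= t1) continue;
    dXf.rows((t0 + off) * B, (t1 + off) * B - 1) +=
      dXcol.submat(t0 * B, j * C, t1 * B - 1, (j + 1) * C - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dXf,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".lstm_fwd")]]
Rcpp::List lstm_fwd(const arma::mat& Xf, int B, int L, const arma::mat& Wx,
                    const arma::mat& Wh, const arma::rowvec& b, int act) {
  const int H = Wh.n_rows;
  mat ZX = Xf * Wx;
  ZX.each_row() += b;
  mat h(B, H, fill::zeros), cc(B, H, fill::zeros);
  // caches: post-activation input/forget/output gates, candidate and its
  // pre-activation, cell state, activated cell state, previous hidden
  mat G(B * L, 3 * H), Gg(B * L, H), ZG(B * L, H);
  mat Cc(B * L, H), ACc(B * L, H), HS(B * L, H);
  mat z(B, 4 * H);
  auto sig1 = [](double v) { return 1.0 / (1.0 + std::exp(-v)); };
  auto actf1 = [act](double v) {
    switch (act) {
      case 1: return v > 0 ? v : 0.2 * v;
      case 2: return 1.0 / (1.0 + std::exp(-v));
      case 3: return std::tanh(v);
      default: return v;
    }
  };
  for (int t = 0; t < L; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    HS.rows(r0, r1) = h;
    z = ZX.rows(r0, r1);
    z += h * Wh;
    for (int j = 0; j < H; ++j) {
      const double* zi = z.colptr(j);
      const double* zf = z.colptr(H + j);
      const double* zgp = z.colptr(2 * H + j);
      const double* zo = z.colptr(3 * H + j);
      double* ccp = cc.colptr(j);
      double* hp = h.colptr(j);
      double* Gi = G.colptr(j) + r0;
      double* Gf = G.colptr(H + j) + r0;
      double* Go = G.colptr(2 * H + j) + r0;
      double* Ggp = Gg.colptr(j) + r0;
      double* ZGp = ZG.colptr(j) + r0;
      double* Ccp = Cc.colptr(j) + r0;
      double* ACp = ACc.colptr(j) + r0;
      for (int r = 0; r < B; ++r) {
        const double iv = sig1(zi[r]), fv = sig1(zf[r]), ov = sig1(zo[r]);
        const double gv = actf1(zgp[r]);
        const double cv = fv * ccp[r] + iv * gv;
        const double av = actf1(cv);
        ccp[r] = cv;
        hp[r] = ov * av;
        Gi[r] = iv; Gf[r] = fv; Go[r] = ov;
        Ggp[r] = gv; ZGp[r] = zgp[r]; Ccp[r] = cv; ACp[r] = av;
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("h") = h, Rcpp::Named("G") = G, Rcpp::Named("Gg") = Gg,
    Rcpp::Named("ZG") = ZG, Rcpp::Named("Cc") = Cc,
    Rcpp::Named("ACc") = ACc, Rcpp::Named("HS") = HS);
}

// [[Rcpp::export(name = ".lstm_bwd")]]
Rcpp::List lstm_bwd(const arma::mat& dY, const arma::mat& Xf, const arma::mat& G,
                    const arma::mat& Gg, const arma::mat& ZG, const arma::mat& Cc,
                    const arma::mat& ACc, const arma::mat& HS, const arma::mat& Wx,
                    const arma::mat& Wh, int B, int L, int act) {
  const int H = Wh.n_rows;
  mat DZ(B * L, 4 * H);
  mat dWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  mat dh = dY, dc(B, H, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    mat ig = G.submat(r0, 0, r1, H - 1);
    mat fg = G.submat(r0, H, r1, 2 * H - 1);
    mat og = G.submat(r0, 2 * H, r1, 3 * H - 1);
    mat gg = Gg.rows(r0, r1);
    mat zg = ZG.rows(r0, r1);
    mat cc = Cc.rows(r0, r1);
    mat ac = ACc.rows(r0, r1);
    mat c_prev = (t > 0) ? mat(Cc.rows(r0 - B, r0 - 1))
                         : mat(B, H, fill::zeros);
    dc += dh % og % act_d(cc, ac, act);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = (dc % gg) % (ig % (1.0 - ig));
    dz.cols(H, 2 * H - 1) = (dc % c_prev) % (fg % (1.0 - fg));
    dz.cols(2 * H, 3 * H - 1) = (dc % ig) % act_d(zg, gg, act);
    dz.cols(3 * H, 4 * H - 1) = (dh % ac) % (og % (1.0 - og));
    DZ.rows(r0, r1) = dz;
    dWh += HS.rows(r0, r1).t() * dz;
    dh = dz * Wh.t();
    dc = dc % fg;
  }
  mat dXf = DZ * Wx.t();
  mat dWx = Xf.t() * DZ;
  rowvec db = sum(DZ, 0);
  return Rcpp::List::create(
    Rcpp::Named("dX") = dXf, Rcpp::Named("dWx") = dWx,
    Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
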