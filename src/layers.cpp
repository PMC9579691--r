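// Network layer primitives: 1-D convolution (same padding), group
// normalisation, single-direction LSTM, and 1-D max pooling, each with an
// explicit backward pass.  All batch tensors are arma::cube with dimensions
// (samples N, channels C, positions L); R arrays of dim c(N, C, L) map onto
// this layout directly.
//
// The time-critical inner products are hoisted out of the per-timestep
// loops into single BLAS calls wherever the recurrence allows it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Stack the L slices of a cube into an (N*L) x C matrix, row block t = slice t.
static mat stack_slices(const cube& X) {
  const uword N = X.n_rows, C = X.n_cols, L = X.n_slices;
  mat M(N * L, C);
  for (uword t = 0; t < L; ++t) M.rows(t * N, (t + 1) * N - 1) = X.slice(t);
  return M;
}

// ---------------------------------------------------------------- conv1d ---

// W has (C * K) rows, kernel-offset-major in blocks of C; K must be odd
// (enforced R-side).  Output length equals input length (zero padding).
// [[Rcpp::export]]
Rcpp::List conv1d_forward_cpp(const arma::cube& X, const arma::mat& W,
                              const arma::rowvec& b) {
  const uword N = X.n_rows, C = X.n_cols, L = X.n_slices;
  const uword K = W.n_rows / C;
  const uword F = W.n_cols;
  const int pad = ((int)K - 1) / 2;

  const mat Xm = stack_slices(X);
  mat M(N * L, C * K, fill::zeros);  // im2col, row = (position t, sample n)
  for (uword k = 0; k < K; ++k) {
    // source position s = t + k - pad; valid t range is contiguous, and so
    // are the corresponding row blocks, so one copy per kernel offset.
    const int off = (int)k - pad;
    const uword t0 = (uword)std::max(0, -off);
    const uword t1 = (uword)std::min((int)L - 1, (int)L - 1 - off);
    if (t0 > t1) continue;
    M.submat(t0 * N, k * C, (t1 + 1) * N - 1, (k + 1) * C - 1) =
      Xm.rows((t0 + off) * N, (t1 + off + 1) * N - 1);
  }
  mat Ym = M * W;
  Ym.each_row() += b;
  cube Y(N, F, L);
  for (uword t = 0; t < L; ++t) Y.slice(t) = Ym.rows(t * N, (t + 1) * N - 1);
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("M") = M);
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::mat& M, const arma::mat& W,
                               const arma::cube& dY, const int C_in) {
  const uword N = dY.n_rows, L = dY.n_slices;
  const uword C = (uword)C_in;
  const uword K = W.n_rows / C;
  const int pad = ((int)K - 1) / 2;

  const mat dYm = stack_slices(dY);
  mat dW = M.t() * dYm;
  rowvec db = sum(dYm, 0);
  mat dM = dYm * W.t();

  mat dXm(N * L, C, fill::zeros);  // col2im scatter-add, blockwise
  for (uword k = 0; k < K; ++k) {
    const int off = (int)k - pad;
    const uword t0 = (uword)std::max(0, -off);
    const uword t1 = (uword)std::min((int)L - 1, (int)L - 1 - off);
    if (t0 > t1) continue;
    dXm.rows((t0 + off) * N, (t1 + off + 1) * N - 1) +=
      dM.submat(t0 * N, k * C, (t1 + 1) * N - 1, (k + 1) * C - 1);
  }
  cube dX(N, C, L);
  for (uword t = 0; t < L; ++t) dX.slice(t) = dXm.rows(t * N, (t + 1) * N - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ------------------------------------------------------------- groupnorm ---

// Normalises each sample over channel groups jointly with the length axis
// (the standard group-norm reduction set), then applies per-channel affine.
// [[Rcpp::export]]
Rcpp::List groupnorm_forward_cpp(const arma::cube& X, const arma::vec& gamma,
                                 const arma::vec& beta, const int G,
                                 const double eps) {
  const uword N = X.n_rows, C = X.n_cols, L = X.n_slices;
  const uword cg = C / (uword)G;
  const double m = (double)(cg * L);

  cube Xhat(N, C, L);
  mat ivar(N, (uword)G);
  for (uword g = 0; g < (uword)G; ++g) {
    const uword c0 = g * cg, c1 = (g + 1) * cg - 1;
    vec s(N, fill::zeros), ss(N, fill::zeros);
    for (uword t = 0; t < L; ++t) {
      const mat sub = X.slice(t).cols(c0, c1);
      s += sum(sub, 1);
      ss += sum(square(sub), 1);
    }
    const vec mu = s / m;
    const vec iv = 1.0 / sqrt(ss / m - square(mu) + eps);
    ivar.col(g) = iv;
    for (uword t = 0; t < L; ++t) {
      mat sub = X.slice(t).cols(c0, c1);
      sub.each_col() -= mu;
      sub.each_col() %= iv;
      Xhat.slice(t).cols(c0, c1) = sub;
    }
  }
  cube Y = Xhat;
  for (uword t = 0; t < L; ++t) {
    Y.slice(t).each_row() %= gamma.t();
    Y.slice(t).each_row() += beta.t();
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("Xhat") = Xhat,
                            Rcpp::Named("ivar") = ivar);
}

// [[Rcpp::export]]
Rcpp::List groupnorm_backward_cpp(const arma::cube& dY, const arma::cube& Xhat,
                                  const arma::mat& ivar, const arma::vec& gamma,
                                  const int G) {
  const uword N = dY.n_rows, C = dY.n_cols, L = dY.n_slices;
  const uword cg = C / (uword)G;
  const double m = (double)(cg * L);

  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    dgamma += sum(dY.slice(t) % Xhat.slice(t), 0).t();
    dbeta += sum(dY.slice(t), 0).t();
  }

  cube dX(N, C, L);
  for (uword g = 0; g < (uword)G; ++g) {
    const uword c0 = g * cg, c1 = (g + 1) * cg - 1;
    const rowvec gam = gamma.subvec(c0, c1).t();
    vec s1(N, fill::zeros), s2(N, fill::zeros);
    for (uword t = 0; t < L; ++t) {
      mat dxh = dY.slice(t).cols(c0, c1);
      dxh.each_row() %= gam;
      s1 += sum(dxh, 1);
      s2 += sum(dxh % Xhat.slice(t).cols(c0, c1), 1);
    }
    const vec iv_m = ivar.col(g) / m;
    for (uword t = 0; t < L; ++t) {
      mat dxh = dY.slice(t).cols(c0, c1);
      dxh.each_row() %= gam;
      mat term = dxh * m;
      term.each_col() -= s1;
      mat xs = Xhat.slice(t).cols(c0, c1);
      xs.each_col() %= s2;
      term -= xs;
      term.each_col() %= iv_m;
      dX.slice(t).cols(c0, c1) = term;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// ------------------------------------------------------------------ lstm ---

// Single direction; the R wrapper reverses time for the backward strand of a
// BiLSTM.  Gate order in the 4H-wide blocks is [input, forget, cell, output].
// The input projection X * Wx is one BLAS call for all timesteps.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& b) {
  const uword N = X.n_rows, L = X.n_slices;
  const uword H = Wh.n_rows;

  mat XW = stack_slices(X) * Wx;
  XW.each_row() += b;

  cube Hs(N, H, L), Cs(N, H, L), Tc(N, H, L), Gs(N, 4 * H, L);
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    mat A = XW.rows(t * N, (t + 1) * N - 1) + h * Wh;
    A.cols(0, 2 * H - 1) = sigm(A.cols(0, 2 * H - 1));        // i, f
    A.cols(2 * H, 3 * H - 1) = tanh(A.cols(2 * H, 3 * H - 1)); // g
    A.cols(3 * H, 4 * H - 1) = sigm(A.cols(3 * H, 4 * H - 1)); // o
    c = A.cols(H, 2 * H - 1) % c + A.cols(0, H - 1) % A.cols(2 * H, 3 * H - 1);
    const mat tc = tanh(c);
    h = A.cols(3 * H, 4 * H - 1) % tc;
    Gs.slice(t) = A;
    Cs.slice(t) = c;
    Tc.slice(t) = tc;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("Tc") = Tc, Rcpp::Named("G") = Gs);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::cube& Hs,
                             const arma::cube& Cs, const arma::cube& Tc,
                             const arma::cube& Gs, const arma::cube& dH) {
  const uword N = X.n_rows, D = X.n_cols, L = X.n_slices;
  const uword H = Wh.n_rows;

  mat dAm(N * L, 4 * H);
  mat dWh(H, 4 * H, fill::zeros);
  mat dh_next(N, H, fill::zeros), dc_next(N, H, fill::zeros);

  for (sword t = (sword)L - 1; t >= 0; --t) {
    const mat i = Gs.slice(t).cols(0, H - 1);
    const mat f = Gs.slice(t).cols(H, 2 * H - 1);
    const mat g = Gs.slice(t).cols(2 * H, 3 * H - 1);
    const mat o = Gs.slice(t).cols(3 * H, 4 * H - 1);
    const mat& tc = Tc.slice(t);

    const mat dh = dH.slice(t) + dh_next;
    const mat do_ = dh % tc;
    const mat dc = dc_next + dh % o % (1.0 - tc % tc);
    const mat di = dc % g;
    const mat dg = dc % i;

    mat dA(N, 4 * H);
    dA.cols(0, H - 1) = di % i % (1.0 - i);
    if (t == 0) {
      dA.cols(H, 2 * H - 1).zeros();  // df % f % (1-f) with c_{-1} = 0
    } else {
      dA.cols(H, 2 * H - 1) = (dc % Cs.slice(t - 1)) % f % (1.0 - f);
    }
    dA.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);

    if (t > 0) dWh += Hs.slice(t - 1).t() * dA;
    dAm.rows(t * N, (t + 1) * N - 1) = dA;
    dh_next = dA * Wh.t();
    dc_next = dc % f;
  }

  const mat Xm = stack_slices(X);
  mat dWx = Xm.t() * dAm;
  rowvec db = sum(dAm, 0);
  mat dXm = dAm * Wx.t();
  cube dX(N, D, L);
  for (uword t = 0; t < L; ++t) dX.slice(t) = dXm.rows(t * N, (t + 1) * N - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}

// --------------------------------------------------------------- maxpool ---

// Non-overlapping windows of size P (stride P); a trailing remainder shorter
// than P is dropped, matching floor(L / P) output positions.  First maximum
// wins on ties.
// [[Rcpp::export]]
Rcpp::List maxpool1d_forward_cpp(const arma::cube& X, const int P) {
  const uword N = X.n_rows, C = X.n_cols, L = X.n_slices;
  const uword Lp = L / (uword)P;

  cube Y(N, C, Lp), A(N, C, Lp);
  for (uword t = 0; t < Lp; ++t) {
    mat best = X.slice(t * P);
    mat arg(N, C);
    arg.fill((double)(t * P));
    for (uword p = 1; p < (uword)P; ++p) {
      const mat& cand = X.slice(t * P + p);
      const uvec idx = find(cand > best);
      best.elem(idx) = cand.elem(idx);
      arg.elem(idx).fill((double)(t * P + p));
    }
    Y.slice(t) = best;
    A.slice(t) = arg;
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
arma::cube maxpool1d_backward_cpp(const arma::cube& dY, const arma::cube& A,
                                  const int P, const int L_in) {
  const uword N = dY.n_rows, C = dY.n_cols, Lp = dY.n_slices;
  cube dX(N, C, (uword)L_in, fill::zeros);
  for (uword t = 0; t < Lp; ++t) {
    for (uword p = 0; p < (uword)P; ++p) {
      const uword s = t * P + p;
      const uvec idx = find(A.slice(t) == (double)s);
      if (idx.n_elem == 0) continue;
      mat tmp = dX.slice(s);
      tmp.elem(idx) += dY.slice(t).elem(idx);
      dX.slice(s) = tmp;
    }
  }
  return dX;
}
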