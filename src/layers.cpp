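// Layer primitives for the inception-residual + LSTM network.
//
// Activations are passed as cubes of dimension L x C x B (position x
// channel x batch).  All layers implement an explicit backward pass; the
// composition into the full architecture and the optimiser live in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// im2col for 1-D convolution with zero ("same") padding along the position
// axis: row (b*L + t) holds the K*Cin receptive-field values for output
// position t of batch item b, ordered k-major then channel.
static mat im2col1d(const cube& x, const int K) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int pad = (K - 1) / 2;
  mat col(B * L, K * Cin, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xb = x.slice(b);
    for (int k = 0; k < K; ++k) {
      const int lo = std::max(0, pad - k);            // first valid t
      const int hi = std::min(L - 1, L - 1 + pad - k); // last valid t
      if (lo > hi) continue;
      // source rows t + k - pad for t in [lo, hi]
      col.submat(b * L + lo, k * Cin, b * L + hi, (k + 1) * Cin - 1) =
        xb.rows(lo + k - pad, hi + k - pad);
    }
  }
  return col;
}

// [[Rcpp::export]]
List conv1d_forward(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b) {
  const int L = x.n_rows, B = x.n_slices;
  const int Cout = W.n_cols;
  const int K = W.n_rows / x.n_cols;
  mat col = im2col1d(x, K);
  mat Y = col * W;                 // (B*L) x Cout
  Y.each_row() += b.t();
  cube y(L, Cout, B);
  for (int bb = 0; bb < B; ++bb) y.slice(bb) = Y.rows(bb * L, (bb + 1) * L - 1);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List conv1d_backward(const arma::cube& x, const arma::mat& W,
                     const arma::cube& dy) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int Cout = W.n_cols;
  const int K = W.n_rows / Cin;
  const int pad = (K - 1) / 2;
  mat col = im2col1d(x, K);
  mat dY(B * L, Cout);
  for (int bb = 0; bb < B; ++bb) dY.rows(bb * L, (bb + 1) * L - 1) = dy.slice(bb);
  mat dW = col.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcol = dY * W.t();           // (B*L) x (K*Cin)
  cube dx(L, Cin, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      const int lo = std::max(0, pad - k);
      const int hi = std::min(L - 1, L - 1 + pad - k);
      if (lo > hi) continue;
      dx.slice(b).rows(lo + k - pad, hi + k - pad) +=
        dcol.submat(b * L + lo, k * Cin, b * L + hi, (k + 1) * Cin - 1);
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Max-pool of width 2, stride 2, along the position axis; a trailing odd
// position is dropped.  Argmax indices (0-based row within input) kept for
// the backward scatter.
// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& x) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int Lo = L / 2;
  cube y(Lo, C, B);
  cube idx(Lo, C, B);   // 0-based input row of each max, stored as double
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c) {
        const double a0 = x(2 * t, c, b), a1 = x(2 * t + 1, c, b);
        if (a0 >= a1) { y(t, c, b) = a0; idx(t, c, b) = 2 * t; }
        else          { y(t, c, b) = a1; idx(t, c, b) = 2 * t + 1; }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& idx, const arma::cube& dy,
                             const int Lin) {
  const int Lo = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  cube dx(Lin, C, B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lo; ++t)
      for (int c = 0; c < C; ++c)
        dx((uword)idx(t, c, b), c, b) += dy(t, c, b);
  return dx;
}

// Batch normalisation per channel, statistics over positions and batch.
// [[Rcpp::export]]
List bn_forward(const arma::cube& x, const arma::vec& gamma,
                const arma::vec& beta, const bool training,
                const arma::vec& run_mean, const arma::vec& run_var,
                const double eps) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  vec mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        s += accu(x.slice(b).col(c));
        s2 += accu(square(x.slice(b).col(c)));
      }
      const double n = (double)L * B;
      mu(c) = s / n;
      va(c) = s2 / n - mu(c) * mu(c);
      if (va(c) < 0) va(c) = 0;
    }
  } else { mu = run_mean; va = run_var; }
  cube xhat(L, C, B), y(L, C, B);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(va(c) + eps);
    for (int b = 0; b < B; ++b) {
      xhat.slice(b).col(c) = (x.slice(b).col(c) - mu(c)) * inv;
      y.slice(b).col(c) = gamma(c) * xhat.slice(b).col(c) + beta(c);
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = va);
}

// [[Rcpp::export]]
List bn_backward(const arma::cube& xhat, const arma::vec& gamma,
                 const arma::vec& var, const arma::cube& dy,
                 const double eps) {
  const int L = xhat.n_rows, C = xhat.n_cols, B = xhat.n_slices;
  const double n = (double)L * B;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  cube dx(L, C, B);
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      sdy += accu(dy.slice(b).col(c));
      sdyx += accu(dy.slice(b).col(c) % xhat.slice(b).col(c));
    }
    dbeta(c) = sdy;
    dgamma(c) = sdyx;
    const double inv = gamma(c) / std::sqrt(var(c) + eps);
    for (int b = 0; b < B; ++b) {
      dx.slice(b).col(c) = inv * (dy.slice(b).col(c) - sdy / n -
        xhat.slice(b).col(c) * (sdyx / n));
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// LSTM over the position axis; input cube T x C x B, returns the final
// hidden state (B x H).  Gate order in the packed weight matrices is
// (input, forget, cell, output).
// [[Rcpp::export]]
List lstm_forward(const arma::cube& x, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b) {
  const int T = x.n_rows, B = x.n_slices;
  const int H = Wh.n_rows;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  cube gates(B, 4 * H, T);   // post-nonlinearity gate values
  cube hs(B, H, T), cs(B, H, T);
  for (int t = 0; t < T; ++t) {
    mat xt(B, x.n_cols);
    for (int bb = 0; bb < B; ++bb) xt.row(bb) = x.slice(bb).row(t);
    mat z = xt * Wx + h * Wh;
    z.each_row() += b.t();
    mat i = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-z.cols(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    gates.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    hs.slice(t) = h;
    cs.slice(t) = c;
  }
  return List::create(_["h"] = h, _["gates"] = gates, _["hs"] = hs,
                      _["cs"] = cs);
}

// [[Rcpp::export]]
List lstm_backward(const arma::cube& x, const arma::mat& Wx,
                   const arma::mat& Wh, const arma::cube& gates,
                   const arma::cube& hs, const arma::cube& cs,
                   const arma::mat& dh_final) {
  const int T = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int H = Wh.n_rows;
  mat dWx(C, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  cube dx(T, C, B, fill::zeros);
  mat dh = dh_final, dc(B, H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat i = gates.slice(t).cols(0, H - 1);
    const mat f = gates.slice(t).cols(H, 2 * H - 1);
    const mat g = gates.slice(t).cols(2 * H, 3 * H - 1);
    const mat o = gates.slice(t).cols(3 * H, 4 * H - 1);
    const mat ct = cs.slice(t);
    const mat tc = tanh(ct);
    const mat cprev = (t == 0) ? mat(B, H, fill::zeros) : cs.slice(t - 1);
    const mat hprev = (t == 0) ? mat(B, H, fill::zeros) : hs.slice(t - 1);
    mat dct = dc + dh % o % (1.0 - tc % tc);
    mat do_ = dh % tc;
    mat di = dct % g, df = dct % cprev, dg = dct % i;
    // pre-activation gradients
    mat dzi = di % i % (1.0 - i);
    mat dzf = df % f % (1.0 - f);
    mat dzg = dg % (1.0 - g % g);
    mat dzo = do_ % o % (1.0 - o);
    mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo)); // B x 4H
    mat xt(B, C);
    for (int bb = 0; bb < B; ++bb) xt.row(bb) = x.slice(bb).row(t);
    dWx += xt.t() * dz;
    dWh += hprev.t() * dz;
    db += sum(dz, 0).t();
    mat dxt = dz * Wx.t();
    for (int bb = 0; bb < B; ++bb) dx.slice(bb).row(t) = dxt.row(bb);
    dh = dz * Wh.t();
    dc = dct % f;
  }
  return List::create(_["dx"] = dx, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
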