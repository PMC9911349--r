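#include <Rcpp.h>
using namespace Rcpp;

// One-hot sequence matrices are L x 4 (row = position, col = base A,C,G,T).
// Filters are stored as a (width*4) x F matrix; the row index of offset k
// (0-based) and base b is k*4 + b, matching the flattening used in R.
//
// Pooling modes:
//   "max"    - global max over windows, then ReLU (presence detector)
//   "avgmax" - windows are tiled into regions of pool_width; per region the
//              max activation is taken, ReLU'd, and the region values are
//              averaged (motif-count sensitive, sharp gradients)

static inline double window_act(const double* X, int L, const double* w,
                                int width, int t, double bias) {
  double a = bias;
  for (int k = 0; k < width; ++k) {
    const double* xr = X + (t + k);
    const double* wr = w + k * 4;
    a += xr[0] * wr[0] + xr[L] * wr[1] + xr[2 * L] * wr[2] + xr[3 * L] * wr[3];
  }
  return a;
}

// [[Rcpp::export]]
List conv_pool_forward(NumericMatrix X, NumericMatrix W, NumericVector b,
                       std::string pool, int pool_width) {
  const int L = X.nrow();
  const int F = W.ncol();
  const int width = W.nrow() / 4;
  const int n_win = L - width + 1;
  NumericVector pooled(F);
  if (n_win <= 0) return List::create(_["pooled"] = pooled, _["n_windows"] = 0);
  const double* Xp = &X(0, 0);
  if (pool == "max") {
    for (int f = 0; f < F; ++f) {
      const double* w = &W(0, f);
      double best = R_NegInf;
      for (int t = 0; t < n_win; ++t) {
        double a = window_act(Xp, L, w, width, t, b[f]);
        if (a > best) best = a;
      }
      pooled[f] = best > 0 ? best : 0.0;
    }
  } else {
    const int n_reg = (n_win + pool_width - 1) / pool_width;
    for (int f = 0; f < F; ++f) {
      const double* w = &W(0, f);
      double acc = 0.0;
      for (int r = 0; r < n_reg; ++r) {
        const int t0 = r * pool_width;
        const int t1 = std::min(t0 + pool_width, n_win);
        double best = R_NegInf;
        for (int t = t0; t < t1; ++t) {
          double a = window_act(Xp, L, w, width, t, b[f]);
          if (a > best) best = a;
        }
        if (best > 0) acc += best;
      }
      pooled[f] = acc / n_reg;
    }
  }
  return List::create(_["pooled"] = pooled, _["n_windows"] = n_win);
}

// Gradient of pooled output w.r.t. W and b for one sequence, given the
// upstream gradient dh (length F). Recomputes activations and argmaxes.
// [[Rcpp::export]]
List conv_pool_backward(NumericMatrix X, NumericMatrix W, NumericVector b,
                        NumericVector dh, std::string pool, int pool_width) {
  const int L = X.nrow();
  const int F = W.ncol();
  const int width = W.nrow() / 4;
  const int n_win = L - width + 1;
  NumericMatrix gW(W.nrow(), F);
  NumericVector gb(F);
  if (n_win <= 0) return List::create(_["gW"] = gW, _["gb"] = gb);
  const double* Xp = &X(0, 0);
  for (int f = 0; f < F; ++f) {
    if (dh[f] == 0.0) continue;
    const double* w = &W(0, f);
    if (pool == "max") {
      double best = R_NegInf; int besti = 0;
      for (int t = 0; t < n_win; ++t) {
        double a = window_act(Xp, L, w, width, t, b[f]);
        if (a > best) { best = a; besti = t; }
      }
      if (best > 0) {
        for (int k = 0; k < width; ++k) {
          const double* xr = Xp + (besti + k);
          gW(k * 4 + 0, f) += dh[f] * xr[0];
          gW(k * 4 + 1, f) += dh[f] * xr[L];
          gW(k * 4 + 2, f) += dh[f] * xr[2 * L];
          gW(k * 4 + 3, f) += dh[f] * xr[3 * L];
        }
        gb[f] += dh[f];
      }
    } else {
      const int n_reg = (n_win + pool_width - 1) / pool_width;
      const double scale = dh[f] / n_reg;
      for (int r = 0; r < n_reg; ++r) {
        const int t0 = r * pool_width;
        const int t1 = std::min(t0 + pool_width, n_win);
        double best = R_NegInf; int besti = t0;
        for (int t = t0; t < t1; ++t) {
          double a = window_act(Xp, L, w, width, t, b[f]);
          if (a > best) { best = a; besti = t; }
        }
        if (best > 0) {
          for (int k = 0; k < width; ++k) {
            const double* xr = Xp + (besti + k);
            gW(k * 4 + 0, f) += scale * xr[0];
            gW(k * 4 + 1, f) += scale * xr[L];
            gW(k * 4 + 2, f) += scale * xr[2 * L];
            gW(k * 4 + 3, f) += scale * xr[3 * L];
          }
          gb[f] += scale;
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb);
}

// All window activations of every filter (pre-ReLU): (n_win x F) matrix.
// Used for first-layer motif extraction.
// [[Rcpp::export]]
NumericMatrix conv_activations(NumericMatrix X, NumericMatrix W,
                               NumericVector b) {
  const int L = X.nrow();
  const int F = W.ncol();
  const int width = W.nrow() / 4;
  const int n_win = L - width + 1;
  if (n_win <= 0) return NumericMatrix(0, F);
  NumericMatrix A(n_win, F);
  const double* Xp = &X(0, 0);
  for (int f = 0; f < F; ++f) {
    const double* w = &W(0, f);
    for (int t = 0; t < n_win; ++t) A(t, f) = window_act(Xp, L, w, width, t, b[f]);
  }
  return A;
}
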