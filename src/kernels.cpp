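// Low-level numerical kernels for the RU-Net graph and the contour metrics.
//
// Feature maps are dense double arrays with dim = c(H, W, C, B) in R's
// column-major layout (H fastest).  Convolution weights are stored as a
// (kh*kw*Cin) x Cout matrix whose row index is k = i + kh*(j + kw*ci),
// i.e. kernel row fastest, then kernel column, then input channel.  All
// convolutions are stride 1 with zero "same" padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D feature array");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

static NumericVector alloc4(int H, int W, int C, int B) {
  NumericVector y(static_cast<R_xlen_t>(H) * W * C * B);
  y.attr("dim") = IntegerVector::create(H, W, C, B);
  return y;
}

// Convolutions are evaluated blockwise over contiguous column (w) ranges of
// each sample: the im2col patch matrix of a block is small enough to stay in
// cache, so the GEMM is compute- rather than memory-bound.  Block rows are
// indexed by (h, w) with h fastest; block columns by k = (i, j, ci).
static void im2col_block(const double *xb, int H, int W, int C, int kh,
                         int kw, int w0, int wcnt, arma::mat &M) {
  const int ph = kh / 2, pw = kw / 2;
  M.set_size(static_cast<size_t>(H) * wcnt, static_cast<size_t>(kh) * kw * C);
  for (int ci = 0; ci < C; ++ci) {
    const double *xc0 = xb + static_cast<size_t>(ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        double *Mcol = M.colptr(k);
        for (int wq = 0; wq < wcnt; ++wq) {
          const int xw = w0 + wq + j - pw;
          double *Mc = Mcol + static_cast<size_t>(wq) * H;
          if (xw < 0 || xw >= W) {
            std::fill(Mc, Mc + H, 0.0);
            continue;
          }
          const double *xc = xc0 + static_cast<size_t>(xw) * H;
          const int di = i - ph;
          if (di == 0) {
            std::memcpy(Mc, xc, sizeof(double) * H);
          } else {
            for (int h = 0; h < H; ++h) {
              const int xh = h + di;
              Mc[h] = (xh >= 0 && xh < H) ? xc[xh] : 0.0;
            }
          }
        }
      }
    }
  }
}

static int block_width(int H, int W, int K) {
  // aim for ~1.5 MB patch blocks
  int wb = static_cast<int>(1.5e6 / (sizeof(double) * static_cast<double>(H) * K));
  if (wb < 4) wb = 4;
  if (wb > W) wb = W;
  return wb;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, const arma::mat &w,
                         const arma::vec &bias, int kh, int kw) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  const int K = kh * kw * C;
  if (static_cast<int>(w.n_rows) != K)
    stop("weight rows (%d) do not match kh*kw*Cin (%d)", (int)w.n_rows, K);
  const int Cout = w.n_cols;
  if (static_cast<int>(bias.n_elem) != Cout) stop("bias length mismatch");

  NumericVector y = alloc4(H, W, Cout, B);
  const size_t plane = static_cast<size_t>(H) * W;
  const int wb = block_width(H, W, K);
  static arma::mat M, Y;
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + static_cast<size_t>(b) * C * plane;
    double *yb = y.begin() + static_cast<size_t>(b) * Cout * plane;
    for (int w0 = 0; w0 < W; w0 += wb) {
      const int wcnt = std::min(wb, W - w0);
      im2col_block(xb, H, W, C, kh, kw, w0, wcnt, M);
      Y = M * w;
      Y.each_row() += bias.t();
      for (int co = 0; co < Cout; ++co)
        std::memcpy(yb + static_cast<size_t>(co) * plane +
                        static_cast<size_t>(w0) * H,
                    Y.colptr(co), sizeof(double) * H * wcnt);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, const arma::mat &w, NumericVector gy,
                int kh, int kw) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  int gH, gW, Cout, gB;
  get_dims4(gy, gH, gW, Cout, gB);
  if (gH != H || gW != W || gB != B) stop("gradient shape mismatch");
  const int K = kh * kw * C;
  if (static_cast<int>(w.n_rows) != K) stop("weight shape mismatch");
  const size_t plane = static_cast<size_t>(H) * W;
  const int ph = kh / 2, pw = kw / 2;

  NumericVector gx = alloc4(H, W, C, B);
  arma::mat gw(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const int wb = block_width(H, W, K);
  static arma::mat M, G, Gcols;
  double *gxp = gx.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + static_cast<size_t>(b) * C * plane;
    const double *gyb = gy.begin() + static_cast<size_t>(b) * Cout * plane;
    double *gxb = gxp + static_cast<size_t>(b) * C * plane;
    for (int w0 = 0; w0 < W; w0 += wb) {
      const int wcnt = std::min(wb, W - w0);
      // gradient block as (h, w) x co matrix
      G.set_size(static_cast<size_t>(H) * wcnt, Cout);
      for (int co = 0; co < Cout; ++co)
        std::memcpy(G.colptr(co),
                    gyb + static_cast<size_t>(co) * plane +
                        static_cast<size_t>(w0) * H,
                    sizeof(double) * H * wcnt);
      im2col_block(xb, H, W, C, kh, kw, w0, wcnt, M);
      gw += M.t() * G;
      gb += arma::sum(G, 0).t();
      Gcols = G * w.t();
      // col2im scatter (may spill pw columns past the block edges)
      for (int ci = 0; ci < C; ++ci) {
        double *gc0 = gxb + static_cast<size_t>(ci) * plane;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const int k = i + kh * (j + kw * ci);
            const double *Gc = Gcols.colptr(k);
            const int di = i - ph;
            for (int wq = 0; wq < wcnt; ++wq) {
              const int xw = w0 + wq + j - pw;
              if (xw < 0 || xw >= W) continue;
              double *gcol = gc0 + static_cast<size_t>(xw) * H;
              const double *Gq = Gc + static_cast<size_t>(wq) * H;
              if (di == 0) {
                for (int h = 0; h < H; ++h) gcol[h] += Gq[h];
              } else {
                for (int h = 0; h < H; ++h) {
                  const int xh = h + di;
                  if (xh >= 0 && xh < H) gcol[xh] += Gq[h];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector x, NumericVector gy) {
  if (x.size() != gy.size()) stop("shape mismatch");
  NumericVector gx(x.size());
  gx.attr("dim") = gy.attr("dim");
  const double *xp = x.begin(), *gp = gy.begin();
  double *op = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0.0 ? gp[i] : 0.0;
  return gx;
}

// Batch normalization over (H, W, B) per channel.  In training mode batch
// statistics are used and exponential running statistics updated; in
// inference mode the supplied running statistics are used.  Variances are
// population (divide-by-n) throughout.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, const arma::vec &gamma, const arma::vec &beta,
            arma::vec running_mean, arma::vec running_var, double eps,
            double momentum, bool training) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (static_cast<int>(gamma.n_elem) != C) stop("gamma length mismatch");
  const size_t plane = static_cast<size_t>(H) * W;
  const double n = static_cast<double>(plane) * B;

  arma::vec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b) {
        const double *xc = x.begin() + (static_cast<size_t>(b) * C + c) * plane;
        for (size_t t = 0; t < plane; ++t) {
          s += xc[t];
          s2 += xc[t] * xc[t];
        }
      }
      mu[c] = s / n;
      var[c] = s2 / n - mu[c] * mu[c];
      if (var[c] < 0.0) var[c] = 0.0;
      running_mean[c] = (1.0 - momentum) * running_mean[c] + momentum * mu[c];
      running_var[c] = (1.0 - momentum) * running_var[c] + momentum * var[c];
    }
  } else {
    mu = running_mean;
    var = running_var;
  }

  NumericVector y = alloc4(H, W, C, B), xhat = alloc4(H, W, C, B);
  arma::vec istd(C);
  for (int c = 0; c < C; ++c) {
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c], is = istd[c], g = gamma[c], bt = beta[c];
    for (int b = 0; b < B; ++b) {
      const size_t off = (static_cast<size_t>(b) * C + c) * plane;
      const double *xc = x.begin() + off;
      double *yc = y.begin() + off;
      double *hc = xhat.begin() + off;
      for (size_t t = 0; t < plane; ++t) {
        const double xh = (xc[t] - m) * is;
        hc[t] = xh;
        yc[t] = g * xh + bt;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["running_mean"] = running_mean,
                      _["running_var"] = running_var);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector xhat, NumericVector gy, const arma::vec &gamma,
            const arma::vec &istd) {
  int H, W, C, B;
  get_dims4(xhat, H, W, C, B);
  const size_t plane = static_cast<size_t>(H) * W;
  const double n = static_cast<double>(plane) * B;

  NumericVector gx = alloc4(H, W, C, B);
  arma::vec ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int b = 0; b < B; ++b) {
      const size_t off = (static_cast<size_t>(b) * C + c) * plane;
      const double *hc = xhat.begin() + off;
      const double *gc = gy.begin() + off;
      for (size_t t = 0; t < plane; ++t) {
        sg += gc[t];
        sgx += gc[t] * hc[t];
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double k = gamma[c] * istd[c];
    const double mg = sg / n, mgx = sgx / n;
    for (int b = 0; b < B; ++b) {
      const size_t off = (static_cast<size_t>(b) * C + c) * plane;
      const double *hc = xhat.begin() + off;
      const double *gc = gy.begin() + off;
      double *oc = gx.begin() + off;
      for (size_t t = 0; t < plane; ++t)
        oc[t] = k * (gc[t] - mg - hc[t] * mgx);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// 2x2 stride-2 max pooling.  Window positions are scanned in row-major
// order (r0c0, r0c1, r1c0, r1c1) and ties break to the first maximum.
// Stored indices are 0-based linear positions into the input array.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (H % 2 != 0 || W % 2 != 0) stop("spatial dimensions must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, B);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C * B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (static_cast<size_t>(b) * C + c) *
                          static_cast<size_t>(H) * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          // row-major scan within the window
          for (int dr = 0; dr < 2; ++dr) {
            for (int dc = 0; dc < 2; ++dc) {
              const size_t lin = base + static_cast<size_t>(w0 + dc) * H +
                                 (h0 + dr);
              if (xp[lin] > best) {
                best = xp[lin];
                besti = lin;
              }
            }
          }
          yp[o] = best;
          ip[o] = static_cast<int>(besti);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter pooled values to their recorded argmax positions; remaining
// positions are zero.  outdim is the dim of the original (pre-pool) array.
// [[Rcpp::export]]
NumericVector scatter_to(NumericVector pooled, IntegerVector idx,
                         IntegerVector outdim) {
  if (pooled.size() != idx.size()) stop("pooled/index size mismatch");
  R_xlen_t n = 1;
  for (int i = 0; i < outdim.size(); ++i) n *= outdim[i];
  NumericVector y(n);
  y.attr("dim") = outdim;
  double *yp = y.begin();
  const double *pp = pooled.begin();
  const int *ip = idx.begin();
  for (R_xlen_t k = 0; k < pooled.size(); ++k) {
    if (ip[k] < 0 || ip[k] >= n) stop("index out of range");
    yp[ip[k]] += pp[k];
  }
  return y;
}

// Gather values at the recorded positions (adjoint of scatter_to).
// [[Rcpp::export]]
NumericVector gather_from(NumericVector x, IntegerVector idx,
                          IntegerVector outdim) {
  NumericVector y(idx.size());
  y.attr("dim") = outdim;
  const double *xp = x.begin();
  const int *ip = idx.begin();
  double *yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t k = 0; k < idx.size(); ++k) {
    if (ip[k] < 0 || ip[k] >= n) stop("index out of range");
    yp[k] = xp[ip[k]];
  }
  return y;
}

// Directed nearest-neighbour statistics between two point sets (rows are
// points, columns coordinates in mm): returns c(max, mean) of the minimum
// Euclidean distance from each row of a to the set b.
// [[Rcpp::export]]
NumericVector directed_nn_stats(const arma::mat &a, const arma::mat &b) {
  if (a.n_rows == 0 || b.n_rows == 0) stop("empty point set");
  if (a.n_cols != b.n_cols) stop("dimension mismatch");
  double dmax = 0.0, dsum = 0.0;
  for (arma::uword i = 0; i < a.n_rows; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (arma::uword j = 0; j < b.n_rows; ++j) {
      double s = 0.0;
      for (arma::uword k = 0; k < a.n_cols; ++k) {
        const double d = a(i, k) - b(j, k);
        s += d * d;
      }
      if (s < best) best = s;
    }
    best = std::sqrt(best);
    if (best > dmax) dmax = best;
    dsum += best;
  }
  return NumericVector::create(dmax, dsum / a.n_rows);
}
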