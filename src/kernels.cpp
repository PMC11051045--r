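// Numerical kernels for the residual U-Net: im2col convolution (forward and
// backward), batch normalisation, 2x2 max pooling, and 8-connected component
// labelling. Arrays follow R's column-major layout with dims (H, W, C, N) for
// feature maps and (kh, kw, Cin, Cout) for convolution weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Patch matrix M is (Ho*Wo) x (kh*kw*C); row = ho + Ho*wo, col = ki + kh*(kj + kw*c).
// This ordering makes M's column layout match the flattened weight array so the
// convolution is a single GEMM per sample.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        double* col = M.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          double* colw = col + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(colw, colw + Ho, 0.0);
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            colw[ho] = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        const double* col = M.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)H * wi;
          const double* colw = col + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            if (hi >= 0 && hi < H) xcw[hi] += colw[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels but weights expect %d", C, Ci);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), kh * kw * Ci, Co, false, true);
  arma::rowvec bv(b.begin(), Co, false, true);
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat M((size_t)Ho * Wo, kh * kw * Ci);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), kh * kw * Ci, Co, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * Ci * Co);
  dw.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat dWm(dw.begin(), kh * kw * Ci, Co, false, true);
  arma::rowvec dbv(db.begin(), Co, false, true);
  arma::mat M((size_t)Ho * Wo, kh * kw * Ci);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat dY(dy.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    dWm += M.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    col2im_add(dM, dx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batch norm over (H, W, N) per channel; biased variance (standard for BN).
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  NumericVector y(x.size());
  y.attr("dim") = xd;
  double m = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xb = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += xb[i]; s2 += xb[i] * xb[i]; }
    }
    double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    double inv = 1.0 / std::sqrt(v + eps);
    double g = gamma[c], bta = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xb = x.begin() + plane * (c + (size_t)C * n);
      double* yb = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yb[i] = g * (xb[i] - mu) * inv + bta;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], inv = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xb = x.begin() + plane * (c + (size_t)C * n);
      const double* db = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        s1 += db[i];
        s2 += db[i] * (xb[i] - mu) * inv;
      }
    }
    dbeta[c] = s1; dgamma[c] = s2;
    double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xb = x.begin() + plane * (c + (size_t)C * n);
      const double* db = dy.begin() + plane * (c + (size_t)C * n);
      double* dxb = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xh = (xb[i] - mu) * inv;
        dxb[i] = g * inv / m * (m * db[i] - s1 - xh * s2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector bn_infer_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                           NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(rvar[c] + eps);
    double g = gamma[c], bta = beta[c], mu = rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* xb = x.begin() + plane * (c + (size_t)C * n);
      double* yb = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yb[i] = g * (xb[i] - mu) * inv + bta;
    }
  }
  return y;
}

// 2x2 max pool, stride 2; argmax stored for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xb = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = 2 * ho, w0 = 2 * wo;
          double best = xb[h0 + (size_t)H * w0];
          size_t besti = h0 + (size_t)H * w0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t idx = (h0 + di) + (size_t)H * (w0 + dj);
              if (xb[idx] > best) { best = xb[idx]; besti = idx; }
            }
          y[o] = best;
          arg[o] = (int)besti;  // within-plane index
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector arg,
                               IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxb = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          dxb[arg[o]] += dy[o];
          ++o;
        }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) dx[i] = x[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector up2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xb = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yb = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xb[h + (size_t)H * w];
          size_t o = 2 * h + (size_t)Ho * (2 * w);
          yb[o] = v; yb[o + 1] = v;
          yb[o + Ho] = v; yb[o + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector up2_bwd_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* db = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* xb = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t o = 2 * h + (size_t)Ho * (2 * w);
          xb[h + (size_t)H * w] = db[o] + db[o + 1] + db[o + Ho] + db[o + Ho + 1];
        }
    }
  return dx;
}

// 8-connected component labelling of a binary matrix (BFS flood fill).
// Returns an integer matrix of labels 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
      }
    }
  }
  return lab;
}
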