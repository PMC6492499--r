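// Minimal batched 2D convolution / max-pooling primitives for the patch
// classification network, using im2col + BLAS matrix products via Armadillo.
// Activation tensors are R arrays in (H, W, C, N) layout; convolution
// weights are (k, k, Cin, Cout). Zero padding, square kernels.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for one sample: rows = output pixels (ho fastest),
// cols = (kh, kw, c) with kh fastest, matching R's column-major flattening
// of a (k, k, Cin, Cout) weight array.
static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * (kw + k * c);
        double* dst = col.colptr(j);
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * stride - pad + kw;
          double* d = dst + (size_t)Ho * wo;
          if (win < 0 || win >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * win;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * stride - pad + kh;
            d[ho] = (hin < 0 || hin >= H) ? 0.0 : xcol[hin];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_forward_cpp")]]
NumericVector conv_forward_cpp(NumericVector x, NumericVector w,
                               NumericVector b, int stride, int pad,
                               bool relu) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo,
           col);
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false,
                 true);
    Yn = col * Wm;
    Yn.each_row() += arma::rowvec(b.begin(), Cout);
  }
  if (relu) {
    for (R_xlen_t i = 0; i < y.size(); ++i)
      if (y[i] < 0) y[i] = 0;
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward_cpp")]]
List conv_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                       int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  arma::mat dWm((size_t)k * k * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat col(Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo,
           col);
    arma::mat dYn((double*)dy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo,
                  Cout, false, true);
    dWm += col.t() * dYn;
    db += arma::sum(dYn, 0);
    if (!need_dx) continue;
    arma::mat dcol = dYn * Wm.t();  // (Ho*Wo) x (k*k*C)
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int j = kh + k * (kw + k * c);
          const double* src = dcol.colptr(j);
          for (int wo = 0; wo < Wo; ++wo) {
            const int win = wo * stride - pad + kw;
            if (win < 0 || win >= W) continue;
            double* dxcol = dxc + (size_t)H * win;
            const double* s = src + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hin = ho * stride - pad + kh;
              if (hin >= 0 && hin < H) dxcol[hin] += s[ho];
            }
          }
        }
      }
    }
  }
  NumericVector dwR((R_xlen_t)k * k * C * Cout);
  dwR.attr("dim") = IntegerVector::create(k, k, C, Cout);
  std::copy(dWm.begin(), dWm.end(), dwR.begin());
  NumericVector dbR(Cout);
  std::copy(db.begin(), db.end(), dbR.begin());
  if (need_dx)
    return List::create(_["dw"] = dwR, _["db"] = dbR, _["dx"] = dx);
  return List::create(_["dw"] = dwR, _["db"] = dbR, _["dx"] = R_NilValue);
}

// Max pooling, kernel `size`, stride `stride`, no padding. Returns the
// pooled tensor and the 0-based linear index (into the input tensor) of
// each selected maximum, for the backward pass.
// [[Rcpp::export(name = ".maxpool_forward_cpp")]]
List maxpool_forward_cpp(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int kw = 0; kw < size; ++kw) {
            const int win = wo * stride + kw;
            for (int kh = 0; kh < size; ++kh) {
              const int hin = ho * stride + kh;
              const double v = xc[(size_t)H * win + hin];
              if (v > best) { best = v; bi = (size_t)H * win + hin; }
            }
          }
          // column-major output order is (ho, wo, c, n): ho fastest, but we
          // iterate wo outer/ho inner, so compute the index explicitly
          const size_t oi =
              (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          y[oi] = best;
          idx[oi] = (int)(base + bi);
          (void)o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward_cpp")]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dx[idx[i]] += dy[i];
  return dx;
}

// In-place elementwise helpers used by the training loop to avoid copying
// large activation tensors on the R side. The arguments are freshly
// allocated gradient tensors owned by the caller.

// a <- relu(a + b), returning a.
// [[Rcpp::export(name = ".add_relu_inplace_cpp")]]
NumericVector add_relu_inplace_cpp(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = a[i] + b[i];
    a[i] = v > 0 ? v : 0;
  }
  return a;
}

// dy <- dy * (act > 0), the rectified-linear backward, in place.
// [[Rcpp::export(name = ".relu_backward_inplace_cpp")]]
NumericVector relu_backward_inplace_cpp(NumericVector dy, NumericVector act) {
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (act[i] <= 0) dy[i] = 0;
  return dy;
}

// a <- a + b in place.
// [[Rcpp::export(name = ".add_inplace_cpp")]]
NumericVector add_inplace_cpp(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) a[i] += b[i];
  return a;
}

// Fused stem: stride-1 convolution (single input channel) + rectified
// linear + 2x2/2 max pooling, without materializing the full-resolution
// activation map for the whole batch. Each sample's pre-pool plane is
// computed with an im2col + BLAS product into a scratch buffer and pooled
// immediately. Returns the pooled map and, per pooled element, the 0-based
// (h + H*w) plane position of the selected pre-pool maximum.
// [[Rcpp::export(name = ".stem_forward_cpp")]]
List stem_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                      int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)k * k, Cout, false, true);
  arma::mat col((size_t)H * W, (size_t)k * k);
  arma::mat planes((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * n, H, W, 1, k, 1, pad, H, W, col);
    planes = col * Wm;
    planes.each_row() += arma::rowvec(b.begin(), Cout);
    for (int c = 0; c < Cout; ++c) {
      const double* plane = planes.colptr(c);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n);
      int* ic = idx.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2) {
            for (int dh2 = 0; dh2 < 2; ++dh2) {
              const int hh = 2 * ho + dh2, ww = 2 * wo + dw2;
              const double v = plane[(size_t)H * ww + hh];
              if (v > best) { best = v; bi = hh + H * ww; }
            }
          }
          yc[(size_t)Ho * wo + ho] = best > 0 ? best : 0;
          ic[(size_t)Ho * wo + ho] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Backward of the fused stem: gradients flow only to the selected pre-pool
// maxima where the rectified output was positive; accumulates dW and db
// directly from the input patches (dx is never needed for the first layer).
// [[Rcpp::export(name = ".stem_backward_cpp")]]
List stem_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                       NumericVector y, IntegerVector idx, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dwR((R_xlen_t)k * k * Cout);
  dwR.attr("dim") = IntegerVector::create(k, k, 1, Cout);
  NumericVector dbR(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * n;
    for (int c = 0; c < Cout; ++c) {
      const size_t off = (size_t)Ho * Wo * (c + (size_t)Cout * n);
      double* dwc = dwR.begin() + (size_t)k * k * c;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) {
        if (y[off + t] <= 0) continue;
        const double g = dy[off + t];
        if (g == 0) continue;
        const int pos = idx[off + t];
        const int hh = pos % H, ww = pos / H;
        dbR[c] += g;
        for (int kw = 0; kw < k; ++kw) {
          const int win = ww + kw - pad;
          if (win < 0 || win >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hin = hh + kh - pad;
            if (hin < 0 || hin >= H) continue;
            dwc[kh + k * kw] += g * xn[(size_t)H * win + hin];
          }
        }
      }
    }
  }
  return List::create(_["dw"] = dwR, _["db"] = dbR);
}

// Batch normalization over (H, W, N) per channel for (H, W, C, N) tensors.
// In training mode uses batch statistics and returns them (plus the
// normalized tensor for the backward pass); in inference mode uses the
// supplied running statistics, so results are independent of how samples
// are batched. Optionally fuses the rectified-linear activation. The
// transform is applied in place: the input is a freshly allocated
// convolution output owned by the caller.
// [[Rcpp::export(name = ".bn_forward_cpp")]]
List bn_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar, bool training,
                    double eps, bool relu) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y = x;  // in-place transform
  NumericVector mean(C), var(C), invstd(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t t = 0; t < plane; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
      }
      const double m = s / (plane * N);
      mean[c] = m;
      var[c] = s2 / (plane * N) - m * m;
      if (var[c] < 0) var[c] = 0;
      invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mean[c] = rmean[c];
      var[c] = rvar[c];
      invstd[c] = 1.0 / std::sqrt(rvar[c] + eps);
    }
  }
  NumericVector xhat;
  if (training) {
    xhat = NumericVector(x.size());
    xhat.attr("dim") = xd;
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      const double g = gamma[c], b = beta[c], m = mean[c], is = invstd[c];
      if (training) {
        double* hc = xhat.begin() + plane * (c + (size_t)C * n);
        for (size_t t = 0; t < plane; ++t) {
          const double h = (yc[t] - m) * is;
          hc[t] = h;
          double v = g * h + b;
          yc[t] = (relu && v < 0) ? 0 : v;
        }
      } else {
        for (size_t t = 0; t < plane; ++t) {
          double v = g * (yc[t] - m) * is + b;
          yc[t] = (relu && v < 0) ? 0 : v;
        }
      }
    }
  }
  if (training)
    return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                        _["invstd"] = invstd, _["xhat"] = xhat);
  return List::create(_["y"] = y);
}

// Backward of batch normalization (training mode, batch statistics).
// Transforms dy into dx in place (dy is a fresh gradient tensor owned by
// the caller) and returns the parameter gradients.
// [[Rcpp::export(name = ".bn_backward_cpp")]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                     NumericVector invstd) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      for (size_t t = 0; t < plane; ++t) { sg += d[t] * h[t]; sb += d[t]; }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double k = gamma[c] * invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      for (size_t t = 0; t < plane; ++t)
        d[t] = k * (m * d[t] - sb - h[t] * sg);
    }
  }
  return List::create(_["dx"] = dy, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
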