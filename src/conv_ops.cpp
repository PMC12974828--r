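// Dense numerical kernels for the CNN engine.
//
// Feature maps are R arrays with dim (H, W, C, N), column-major, so the
// linear index of (h, w, c, n) is h + H*(w + W*(c + C*n)) (all 0-based).
// Convolution weights: standard conv (k, k, Cin, Cout); depthwise (k, k, C).
// Padding follows the usual "valid" / "same" conventions; under "same",
// padded positions are excluded from pooling windows rather than compared
// as zeros.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct PadSpec {
  int out;        // output spatial size
  int before;     // padding before (top/left)
};

PadSpec pad_spec(int in, int k, int stride, bool same) {
  PadSpec p;
  if (same) {
    p.out = (in + stride - 1) / stride;
    int total = std::max((p.out - 1) * stride + k - in, 0);
    p.before = total / 2;
  } else {
    if (in < k) stop("input size %d smaller than kernel %d under valid padding", in, k);
    p.out = (in - k) / stride + 1;
    p.before = 0;
  }
  return p;
}

inline long idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + (long)H * (w + (long)W * (c + (long)C * n));
}

IntegerVector dims_of(const NumericVector& x) {
  if (!x.hasAttribute("dim")) stop("array input required");
  return x.attr("dim");
}

} // namespace

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, int stride,
                            bool same, Nullable<NumericVector> bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input %d vs kernel %d", C, Cin);
  PadSpec ph = pad_spec(H, kh, stride, same), pw = pad_spec(W, kw, stride, same);
  NumericVector y(ph.out * (long)pw.out * Cout * N);
  y.attr("dim") = IntegerVector::create(ph.out, pw.out, Cout, N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  std::vector<double> b(Cout, 0.0);
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    for (int i = 0; i < Cout; ++i) b[i] = bb[i];
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ow = 0; ow < pw.out; ++ow)
        for (int oh = 0; oh < ph.out; ++oh) {
          double acc = b[co];
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          for (int ci = 0; ci < C; ++ci)
            for (int j = 0; j < kw; ++j) {
              int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < kh; ++i) {
                int hi = h0 + i;
                if (hi < 0 || hi >= H) continue;
                acc += xp[idx4(hi, wi, ci, n, H, W, C)] *
                       wp[i + (long)kh * (j + (long)kw * (ci + (long)Cin * co))];
              }
            }
          yp[idx4(oh, ow, co, n, ph.out, pw.out, Cout)] = acc;
        }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, bool same, bool has_bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int OH = yd[0], OW = yd[1];
  PadSpec ph = pad_spec(H, kh, stride, same), pw = pad_spec(W, kw, stride, same);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double g = dyp[idx4(oh, ow, co, n, OH, OW, Cout)];
          if (has_bias) db[co] += g;
          if (g == 0.0) continue;
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          for (int ci = 0; ci < C; ++ci)
            for (int j = 0; j < kw; ++j) {
              int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < kh; ++i) {
                int hi = h0 + i;
                if (hi < 0 || hi >= H) continue;
                long xi = idx4(hi, wi, ci, n, H, W, C);
                long wi_ = i + (long)kh * (j + (long)kw * (ci + (long)Cin * co));
                dxp[xi] += g * wp[wi_];
                dwp[wi_] += g * xp[xi];
              }
            }
        }
  List out = List::create(Named("dx") = dx, Named("dw") = dw);
  if (has_bias) out["db"] = db;
  return out;
}

// [[Rcpp::export(name = ".depthwise_fw")]]
NumericVector depthwise_fw_cpp(NumericVector x, NumericVector w, int stride,
                               bool same) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cw = wd[2];
  if (Cw != C) stop("channel mismatch in depthwise conv");
  PadSpec ph = pad_spec(H, kh, stride, same), pw = pad_spec(W, kw, stride, same);
  NumericVector y(ph.out * (long)pw.out * C * N);
  y.attr("dim") = IntegerVector::create(ph.out, pw.out, C, N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < pw.out; ++ow)
        for (int oh = 0; oh < ph.out; ++oh) {
          double acc = 0.0;
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          for (int j = 0; j < kw; ++j) {
            int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              acc += xp[idx4(hi, wi, c, n, H, W, C)] *
                     wp[i + (long)kh * (j + (long)kw * c)];
            }
          }
          yp[idx4(oh, ow, c, n, ph.out, pw.out, C)] = acc;
        }
  return y;
}

// [[Rcpp::export(name = ".depthwise_bw")]]
List depthwise_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, bool same) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int OH = yd[0], OW = yd[1];
  PadSpec ph = pad_spec(H, kh, stride, same), pw = pad_spec(W, kw, stride, same);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double g = dyp[idx4(oh, ow, c, n, OH, OW, C)];
          if (g == 0.0) continue;
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          for (int j = 0; j < kw; ++j) {
            int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              long xi = idx4(hi, wi, c, n, H, W, C);
              long wi_ = i + (long)kh * (j + (long)kw * c);
              dxp[xi] += g * wp[wi_];
              dwp[wi_] += g * xp[xi];
            }
          }
        }
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw_cpp(NumericVector x, int win, int stride, bool same) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  PadSpec ph = pad_spec(H, win, stride, same), pw = pad_spec(W, win, stride, same);
  long olen = ph.out * (long)pw.out * C * N;
  NumericVector y(olen);
  IntegerVector idx(olen);
  y.attr("dim") = IntegerVector::create(ph.out, pw.out, C, N);
  const double* xp = x.begin();
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < pw.out; ++ow)
        for (int oh = 0; oh < ph.out; ++oh) {
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          double best = R_NegInf;
          long besti = -1;
          // row-major window scan; strict > keeps the first occurrence on ties
          for (int i = 0; i < win; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            for (int j = 0; j < win; ++j) {
              int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              long xi = idx4(hi, wi, c, n, H, W, C);
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          if (besti < 0) stop("empty pooling window");
          long oi = idx4(oh, ow, c, n, ph.out, pw.out, C);
          y[oi] = best;
          idx[oi] = (int)besti;
          ++o;
        }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw_cpp(NumericVector dy, IntegerVector idx,
                             IntegerVector xdim) {
  long xlen = 1;
  for (int i = 0; i < xdim.size(); ++i) xlen *= xdim[i];
  NumericVector dx(xlen);
  dx.attr("dim") = xdim;
  for (long j = 0; j < dy.size(); ++j) dx[idx[j]] += dy[j];
  return dx;
}

// [[Rcpp::export(name = ".avgtopk_fw")]]
List avgtopk_fw_cpp(NumericVector x, int win, int stride, int K, bool same) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (K < 1) stop("K must be >= 1");
  PadSpec ph = pad_spec(H, win, stride, same), pw = pad_spec(W, win, stride, same);
  long olen = ph.out * (long)pw.out * C * N;
  NumericVector y(olen);
  // K x olen selection cache, -1 marks unused slots (window had < K elements)
  IntegerMatrix sel(K, olen);
  y.attr("dim") = IntegerVector::create(ph.out, pw.out, C, N);
  const double* xp = x.begin();
  std::vector<std::pair<double, long> > vals;
  vals.reserve(win * win);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < pw.out; ++ow)
        for (int oh = 0; oh < ph.out; ++oh) {
          int h0 = oh * stride - ph.before, w0 = ow * stride - pw.before;
          vals.clear();
          // row-major scan order; stable sort keeps it as the tie-break
          for (int i = 0; i < win; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            for (int j = 0; j < win; ++j) {
              int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              vals.push_back(std::make_pair(xp[idx4(hi, wi, c, n, H, W, C)],
                                            idx4(hi, wi, c, n, H, W, C)));
            }
          }
          if (vals.empty()) stop("empty pooling window");
          std::stable_sort(vals.begin(), vals.end(),
                           [](const std::pair<double, long>& a,
                              const std::pair<double, long>& b) {
                             return a.first > b.first;
                           });
          int keff = std::min((int)vals.size(), K);
          double acc = 0.0;
          long oi = idx4(oh, ow, c, n, ph.out, pw.out, C);
          for (int k = 0; k < K; ++k) {
            if (k < keff) {
              acc += vals[k].first;
              sel(k, oi) = (int)vals[k].second;
            } else {
              sel(k, oi) = -1;
            }
          }
          y[oi] = acc / keff;
        }
  return List::create(Named("y") = y, Named("sel") = sel);
}

// [[Rcpp::export(name = ".avgtopk_bw")]]
NumericVector avgtopk_bw_cpp(NumericVector dy, IntegerMatrix sel,
                             IntegerVector xdim) {
  long xlen = 1;
  for (int i = 0; i < xdim.size(); ++i) xlen *= xdim[i];
  NumericVector dx(xlen);
  dx.attr("dim") = xdim;
  int K = sel.nrow();
  if (sel.ncol() != dy.size()) stop("selection cache does not match gradient shape");
  for (long j = 0; j < dy.size(); ++j) {
    int keff = 0;
    for (int k = 0; k < K; ++k) if (sel(k, j) >= 0) ++keff;
    if (keff == 0) stop("corrupt selection cache");
    double g = dy[j] / keff;
    for (int k = 0; k < K; ++k) if (sel(k, j) >= 0) dx[sel(k, j)] += g;
  }
  return dx;
}

// Fused separable convolution: depthwise then pointwise projection.
// Returns the output and the depthwise intermediate (needed for backward).
// [[Rcpp::export(name = ".sepconv_fw")]]
List sepconv_fw_cpp(NumericVector x, NumericVector wd, NumericMatrix wp,
                    int stride, bool same, Nullable<NumericVector> bias) {
  NumericVector d = depthwise_fw_cpp(x, wd, stride, same);
  IntegerVector dd = d.attr("dim");
  int OH = dd[0], OW = dd[1], C = dd[2], N = dd[3];
  int Cout = wp.ncol();
  if (wp.nrow() != C) stop("pointwise weight rows must equal channels");
  long hw = (long)OH * OW;
  NumericVector y(hw * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  const double* dp = d.begin();
  double* yp = y.begin();
  std::vector<double> b(Cout, 0.0);
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    for (int i = 0; i < Cout; ++i) b[i] = bb[i];
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* ys = yp + hw * (co + (long)Cout * n);
      for (long i = 0; i < hw; ++i) ys[i] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        double wv = wp(ci, co);
        if (wv == 0.0) continue;
        const double* ds = dp + hw * (ci + (long)C * n);
        for (long i = 0; i < hw; ++i) ys[i] += wv * ds[i];
      }
    }
  return List::create(Named("y") = y, Named("d") = d);
}

// [[Rcpp::export(name = ".sepconv_bw")]]
List sepconv_bw_cpp(NumericVector x, NumericVector wd, NumericMatrix wp,
                    NumericVector d, NumericVector dy, int stride, bool same,
                    bool has_bias) {
  IntegerVector dd = d.attr("dim");
  int OH = dd[0], OW = dd[1], C = dd[2], N = dd[3];
  int Cout = wp.ncol();
  long hw = (long)OH * OW;
  NumericMatrix dwp(C, Cout);
  NumericVector ddv(d.size());
  ddv.attr("dim") = dd;
  NumericVector db(has_bias ? Cout : 0);
  const double* dp = d.begin();
  const double* dyp = dy.begin();
  double* ddp = ddv.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* gs = dyp + hw * (co + (long)Cout * n);
      if (has_bias) {
        double acc = 0.0;
        for (long i = 0; i < hw; ++i) acc += gs[i];
        db[co] += acc;
      }
      for (int ci = 0; ci < C; ++ci) {
        const double* ds = dp + hw * (ci + (long)C * n);
        double* dds = ddp + hw * (ci + (long)C * n);
        double wv = wp(ci, co);
        double acc = 0.0;
        for (long i = 0; i < hw; ++i) {
          acc += ds[i] * gs[i];
          dds[i] += wv * gs[i];
        }
        dwp(ci, co) += acc;
      }
    }
  List r = depthwise_bw_cpp(x, wd, ddv, stride, same);
  List out = List::create(Named("dx") = r["dx"], Named("dwd") = r["dw"],
                          Named("dwp") = dwp);
  if (has_bias) out["db"] = db;
  return out;
}

// Per-channel mean and (biased) variance over (H, W, N).
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector xd = dims_of(x);
  int C = xd[2], N = xd[3];
  long hw = (long)xd[0] * xd[1];
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + hw * (c + (long)C * n);
      double s = 0.0, s2 = 0.0;
      for (long i = 0; i < hw; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      mu[c] += s; var[c] += s2;
    }
  double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = std::max(var[c] / m - mu[c] * mu[c], 0.0);
  }
  return List::create(Named("mu") = mu, Named("var") = var);
}

// [[Rcpp::export(name = ".bn_fw")]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mu, NumericVector var, double eps) {
  IntegerVector xd = dims_of(x);
  int C = xd[2], N = xd[3];
  long hw = (long)xd[0] * xd[1];
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double inv = 1.0 / std::sqrt(var[c] + eps);
      double g = gamma[c], b = beta[c], m = mu[c];
      long off = hw * (c + (long)C * n);
      for (long i = 0; i < hw; ++i) {
        double h = (xp[off + i] - m) * inv;
        hp[off + i] = h;
        yp[off + i] = g * h + b;
      }
    }
  return List::create(Named("y") = y, Named("xhat") = xhat);
}

// Training-mode batch-norm backward from cached xhat.
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw_cpp(NumericVector xhat, NumericVector dy, NumericVector gamma,
               NumericVector inv_sd) {
  IntegerVector xd = dims_of(xhat);
  int C = xd[2], N = xd[3];
  long hw = (long)xd[0] * xd[1];
  double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C), dx(xhat.size());
  dx.attr("dim") = xd;
  const double* hp = xhat.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long off = hw * (c + (long)C * n);
      double sg = 0.0, sb = 0.0;
      for (long i = 0; i < hw; ++i) {
        sg += dyp[off + i] * hp[off + i];
        sb += dyp[off + i];
      }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long off = hw * (c + (long)C * n);
      double k1 = dbeta[c] / m, k2 = dgamma[c] / m;
      double scale = gamma[c] * inv_sd[c];
      for (long i = 0; i < hw; ++i) {
        dxp[off + i] = scale * (dyp[off + i] - k1 - hp[off + i] * k2);
      }
    }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
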