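// Low-level numerical kernels: im2col convolution (forward / backward),
// bicubic and nearest-neighbour image warping, exact Euclidean distance
// transform, and connected-component labelling. Everything above these
// primitives lives in R.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int s) { return (n + s - 1) / s; }

// TensorFlow-style SAME padding: total pad so that out = ceil(in / stride),
// split with the smaller half at the beginning.
static inline int pad_begin(int n, int k, int s) {
  int o = out_dim(n, s);
  int tot = (o - 1) * s + k - n;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// col layout: row = di + k*dj + k*k*c ; column = io + Ho*jo
static void im2col(const double* x, int H, int W, int C, int k, int s,
                   arma::mat& col) {
  int Ho = out_dim(H, s), Wo = out_dim(W, s);
  int pbh = pad_begin(H, k, s), pbw = pad_begin(W, k, s);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int row = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          int wj = jo * s - pbw + dj;
          if (wj < 0 || wj >= W) continue;
          const double* xcol = xc + (size_t)H * wj;
          for (int io = 0; io < Ho; ++io) {
            int hi = io * s - pbh + di;
            if (hi < 0 || hi >= H) continue;
            col.at(row, io + (size_t)Ho * jo) = xcol[hi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C, int k, int s,
                       double* x) {
  int Ho = out_dim(H, s), Wo = out_dim(W, s);
  int pbh = pad_begin(H, k, s), pbw = pad_begin(W, k, s);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int row = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          int wj = jo * s - pbw + dj;
          if (wj < 0 || wj >= W) continue;
          double* xcol = xc + (size_t)H * wj;
          for (int io = 0; io < Ho; ++io) {
            int hi = io * s - pbh + di;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += col.at(row, io + (size_t)Ho * jo);
          }
        }
      }
    }
  }
}

// x: (H, W, C, N) array; w: Cout x (k*k*C); b: length Cout.
// Returns (Ho, Wo, Cout, N).
// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, IntegerVector xdim,
                               NumericMatrix w, NumericVector b,
                               int k, int s) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = out_dim(H, s), Wo = out_dim(W, s);
  int Cout = w.nrow();
  if (w.ncol() != k * k * C) stop("weight matrix does not match kernel/channels");
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wm(w.begin(), Cout, k * k * C, false);
  arma::mat col(k * k * C, (size_t)Ho * Wo);
  size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, k, s, col);
    arma::mat ym = wm * col;  // Cout x (Ho*Wo)
    double* yp = y.begin() + n * ystep;
    for (int co = 0; co < Cout; ++co) {
      double bc = b[co];
      double* ypc = yp + (size_t)co * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) ypc[p] = ym.at(co, p) + bc;
    }
  }
  return y;
}

// Gradient w.r.t. filter and bias. dy: (Ho, Wo, Cout, N).
// [[Rcpp::export]]
List cpp_conv_bwd_filter(NumericVector x, IntegerVector xdim,
                         NumericVector dy, IntegerVector ydim,
                         int k, int s) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2];
  arma::mat dW(Cout, k * k * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(k * k * C, (size_t)Ho * Wo);
  size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, k, s, col);
    // dy sample as (Ho*Wo) x Cout then transpose access
    const double* dyp = dy.begin() + n * ystep;
    arma::mat dym(const_cast<double*>(dyp), (size_t)Ho * Wo, Cout, false);
    dW += dym.t() * col.t();
    db += arma::sum(dym, 0).t();
  }
  return List::create(Named("dW") = wrap(dW), Named("db") = wrap(db));
}

// Gradient w.r.t. input (also the forward pass of a transposed convolution).
// dy: (Ho, Wo, Cout, N); returns (H, W, C, N).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, IntegerVector ydim,
                                NumericMatrix w, int k, int s,
                                int H, int W) {
  int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2], N = ydim[3];
  int C = w.ncol() / (k * k);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat wm(w.begin(), Cout, k * k * C, false);
  size_t ystep = (size_t)Ho * Wo * Cout, xstep = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + n * ystep;
    arma::mat dym(const_cast<double*>(dyp), (size_t)Ho * Wo, Cout, false);
    arma::mat dcol = wm.t() * dym.t();  // (k*k*C) x (Ho*Wo)
    col2im_add(dcol, H, W, C, k, s, dx.begin() + n * xstep);
  }
  return dx;
}

// ---- image warping -------------------------------------------------------

static inline double cubic_w(double d) {
  const double a = -0.5;  // Catmull-Rom
  d = std::fabs(d);
  if (d <= 1.0) return ((a + 2.0) * d - (a + 3.0)) * d * d + 1.0;
  if (d < 2.0) return a * (((d - 5.0) * d + 8.0) * d - 4.0);
  return 0.0;
}

static inline double pix_at(const NumericMatrix& img, int r, int c,
                            double fill, int border) {
  int H = img.nrow(), W = img.ncol();
  if (r < 0 || r >= H || c < 0 || c >= W) {
    if (border == 1) {
      r = std::min(std::max(r, 0), H - 1);
      c = std::min(std::max(c, 0), W - 1);
      return img(r, c);
    }
    return fill;
  }
  return img(r, c);
}

// map_r/map_c give, for each destination pixel, the (0-based) source
// coordinates. method: 0 nearest, 1 bicubic. border: 0 constant fill,
// 1 replicate edge.
// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix map_r,
                       NumericMatrix map_c, int method, double fill,
                       int border) {
  int Ho = map_r.nrow(), Wo = map_r.ncol();
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double sr = map_r(i, j), sc = map_c(i, j);
      if (method == 0) {
        int r = (int)std::floor(sr + 0.5), c = (int)std::floor(sc + 0.5);
        out(i, j) = pix_at(img, r, c, fill, border);
      } else {
        if (border == 0 && (sr < -2 || sr > H + 1 || sc < -2 || sc > W + 1)) {
          out(i, j) = fill;
          continue;
        }
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        double acc = 0.0;
        for (int m = -1; m <= 2; ++m) {
          double wr = cubic_w(sr - (r0 + m));
          if (wr == 0.0) continue;
          double rowacc = 0.0;
          for (int nn = -1; nn <= 2; ++nn) {
            double wc = cubic_w(sc - (c0 + nn));
            if (wc == 0.0) continue;
            rowacc += wc * pix_at(img, r0 + m, c0 + nn, fill, border);
          }
          acc += wr * rowacc;
        }
        out(i, j) = acc;
      }
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) ------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) {
        kk--;
      } else {
        break;
      }
    }
    kk++;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) kk++;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// Exact Euclidean distance of every pixel to the nearest TRUE pixel.
// All-false mask gives Inf everywhere. Internally a large finite sentinel
// stands in for +Inf so the lower-envelope recursion stays well defined.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  const double BIG = 1e15;
  bool any_true = false;
  arma::mat g(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      g(i, j) = mask(i, j) ? 0.0 : BIG;
      if (mask(i, j)) any_true = true;
    }
  NumericMatrix out(H, W);
  if (!any_true) {
    out.fill(R_PosInf);
    return out;
  }
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = g(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) g(i, j) = std::min(d[i], BIG);
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = g(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// ---- connected components ------------------------------------------------

// Label connected TRUE regions; connectivity 4 or 8. Labels start at 1 in
// scan order; FALSE pixels get 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int q = 0; q < nnb; ++q) {
          int r = p.first + dr8[q], c = p.second + dc8[q];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}
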