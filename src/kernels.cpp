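// Compiled kernels: marker-seeded watershed flooding, grayscale
// morphological reconstruction, regional maxima, 4-connected labeling,
// and the convolution / max-pooling layers of the network.
//
// All image code uses 4-connectivity and column-major (R) layout.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Neighbour offsets, fixed order: up, down, left, right.
static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

// ---------------------------------------------------------------------------
// Marker-seeded watershed (Meyer flooding with ordered queue).
//
// P:    priority surface (e.g. gradient magnitude), H x W
// seeds: integer labels, 0 = unlabeled, > 0 = marker label
//
// Pixels are flooded in increasing priority; ties broken first-in
// first-out. A pixel adjacent to two different basins becomes a ridge
// pixel (label 0 in the output). Ridge pixels do not propagate.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix P, IntegerMatrix seeds) {
  const int H = P.nrow(), W = P.ncol();
  if (seeds.nrow() != H || seeds.ncol() != W)
    stop("priority and seed shapes differ");

  // lab: 0 = undecided, -1 = ridge, > 0 = basin label
  std::vector<int> lab(static_cast<size_t>(H) * W);
  bool any_seed = false;
  for (int i = 0; i < H * W; ++i) {
    lab[i] = seeds[i];
    if (seeds[i] > 0) any_seed = true;
  }
  if (!any_seed) stop("no markers");

  struct Node {
    double p;
    long long seq;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.p != b.p) return a.p > b.p;  // min-heap on priority
      return a.seq > b.seq;              // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> q;
  long long seq = 0;

  // Initial frontier: unlabeled pixels with a labeled neighbour,
  // scanned in column-major order.
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int i = r + H * c;
      if (lab[i] != 0) continue;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (lab[rr + H * cc] > 0) {
          q.push({P[i], seq++, i});
          break;
        }
      }
    }
  }

  while (!q.empty()) {
    const Node nd = q.top();
    q.pop();
    const int i = nd.idx;
    if (lab[i] != 0) continue;  // stale duplicate
    const int r = i % H, c = i / H;

    int found = 0;  // distinct positive neighbour label (0 = none yet)
    bool conflict = false;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const int l = lab[rr + H * cc];
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) { conflict = true; break; }
      }
    }
    if (conflict) {
      lab[i] = -1;  // ridge: belongs to no basin, does not propagate
    } else if (found > 0) {
      lab[i] = found;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        const int j = rr + H * cc;
        if (lab[j] == 0) q.push({P[j], seq++, j});
      }
    }
  }

  IntegerMatrix out(H, W);
  for (int i = 0; i < H * W; ++i) out[i] = lab[i] > 0 ? lab[i] : 0;
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation (hybrid raster/queue algorithm).
// Requires marker <= mask elementwise.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("marker and mask shapes differ");
  NumericMatrix J(clone(marker));
  for (int i = 0; i < H * W; ++i)
    if (J[i] > mask[i]) stop("marker must not exceed mask");

  // forward raster scan (N+: up, left)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double v = J(r, c);
      if (r > 0 && J(r - 1, c) > v) v = J(r - 1, c);
      if (c > 0 && J(r, c - 1) > v) v = J(r, c - 1);
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  // backward raster scan (N-: down, right), queue boundary pixels
  std::queue<int> q;
  for (int c = W - 1; c >= 0; --c) {
    for (int r = H - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < H - 1 && J(r + 1, c) > v) v = J(r + 1, c);
      if (c < W - 1 && J(r, c + 1) > v) v = J(r, c + 1);
      J(r, c) = std::min(v, mask(r, c));
      const bool down = r < H - 1 && J(r + 1, c) < J(r, c) && J(r + 1, c) < mask(r + 1, c);
      const bool right = c < W - 1 && J(r, c + 1) < J(r, c) && J(r, c + 1) < mask(r, c + 1);
      if (down || right) q.push(r + H * c);
    }
  }
  while (!q.empty()) {
    const int i = q.front();
    q.pop();
    const int r = i % H, c = i / H;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        q.push(rr + H * cc);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Regional maxima: connected plateaus (4-connectivity) with no strictly
// greater neighbour.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<char> visited(static_cast<size_t>(H) * W, 0);
  LogicalMatrix out(H, W);
  std::vector<int> plateau;
  std::queue<int> q;

  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      const int i0 = r0 + H * c0;
      if (visited[i0]) continue;
      const double v = img[i0];
      bool is_max = true;
      plateau.clear();
      q.push(i0);
      visited[i0] = 1;
      while (!q.empty()) {
        const int i = q.front();
        q.pop();
        plateau.push_back(i);
        const int r = i % H, c = i / H;
        for (int k = 0; k < 4; ++k) {
          const int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          const int j = rr + H * cc;
          if (img[j] > v) is_max = false;
          else if (img[j] == v && !visited[j]) {
            visited[j] = 1;
            q.push(j);
          }
        }
      }
      if (is_max)
        for (size_t t = 0; t < plateau.size(); ++t) out[plateau[t]] = TRUE;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 4-connected component labeling of a logical mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      const int i0 = r0 + H * c0;
      if (!mask[i0] || lab[i0] != 0) continue;
      lab[i0] = ++next;
      q.push(i0);
      while (!q.empty()) {
        const int i = q.front();
        q.pop();
        const int r = i % H, c = i / H;
        for (int k = 0; k < 4; ++k) {
          const int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          const int j = rr + H * cc;
          if (mask[j] && lab[j] == 0) {
            lab[j] = next;
            q.push(j);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Convolution, stride 1, symmetric zero padding `pad`.
// X: (H, W, Cin, N), Wt: (kh, kw, Cin, Cout), b: length Cout.
// Returns (Ho, Wo, Cout, N) with Ho = H + 2*pad - kh + 1.
//
// Implemented as one GEMM per kernel offset over the whole batch:
// gathering X shifted by (dh, dw) into a (Ho*Wo*N) x Cin matrix keeps
// the GEMMs large enough for BLAS to run near peak. The GEMMs run in
// single precision (inputs are [0,1] activations and O(1) weights, and
// each output sums at most kh*kw*Cin products, so float headroom is
// ample); results are returned as doubles.

// Gather A[(ho,wo,n), ci] = X[ho+dh-pad, wo+dw-pad, ci, n] (zeros
// outside the image).
static void gather_offset(const double* X, int H, int W, int C, int N,
                          int Ho, int Wo, int dh, int dw, int pad,
                          arma::fmat& A) {
  A.zeros();
  const int hs = dh - pad, ws = dw - pad;
  const int h0 = std::max(0, -hs), h1 = std::min(Ho, H - hs);
  const int w0 = std::max(0, -ws), w1 = std::min(Wo, W - ws);
  if (h1 <= h0 || w1 <= w0) return;
  for (int ci = 0; ci < C; ++ci) {
    float* a = A.colptr(ci);
    for (int n = 0; n < N; ++n) {
      const double* xp = X + (static_cast<size_t>(n) * C + ci) * H * W;
      for (int wo = w0; wo < w1; ++wo) {
        const double* src = xp + static_cast<size_t>(wo + ws) * H + (h0 + hs);
        float* dst = a + (static_cast<size_t>(n) * Wo + wo) * Ho + h0;
        for (int h = 0; h < h1 - h0; ++h) dst[h] = static_cast<float>(src[h]);
      }
    }
  }
}

// Scatter-add the transpose of gather_offset.
static void scatter_offset(const arma::fmat& A, double* X, int H, int W,
                           int C, int N, int Ho, int Wo, int dh, int dw,
                           int pad) {
  const int hs = dh - pad, ws = dw - pad;
  const int h0 = std::max(0, -hs), h1 = std::min(Ho, H - hs);
  const int w0 = std::max(0, -ws), w1 = std::min(Wo, W - ws);
  if (h1 <= h0 || w1 <= w0) return;
  for (int ci = 0; ci < C; ++ci) {
    const float* a = A.colptr(ci);
    for (int n = 0; n < N; ++n) {
      double* xp = X + (static_cast<size_t>(n) * C + ci) * H * W;
      for (int wo = w0; wo < w1; ++wo) {
        double* dst = xp + static_cast<size_t>(wo + ws) * H + (h0 + hs);
        const float* src = a + (static_cast<size_t>(n) * Wo + wo) * Ho + h0;
        for (int h = 0; h < h1 - h0; ++h) dst[h] += static_cast<double>(src[h]);
      }
    }
  }
}

// View Y (Ho, Wo, Cout, N) as a (Ho*Wo*N) x Cout matrix with rows in
// (ho, wo, n) order: needs a permuted copy since Cout is the 3rd axis.
static void y_to_rows(const NumericVector& Y, int Ho, int Wo, int C, int N,
                      arma::fmat& R) {
  const size_t plane = static_cast<size_t>(Ho) * Wo;
  for (int co = 0; co < C; ++co) {
    float* r = R.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = Y.begin() + (static_cast<size_t>(n) * C + co) * plane;
      float* dst = r + static_cast<size_t>(n) * plane;
      for (size_t i = 0; i < plane; ++i) dst[i] = static_cast<float>(src[i]);
    }
  }
}

static void rows_to_y(const arma::fmat& R, NumericVector& Y, int Ho, int Wo,
                      int C, int N) {
  const size_t plane = static_cast<size_t>(Ho) * Wo;
  for (int co = 0; co < C; ++co) {
    const float* r = R.colptr(co);
    for (int n = 0; n < N; ++n) {
      double* dst = Y.begin() + (static_cast<size_t>(n) * C + co) * plane;
      const float* src = r + static_cast<size_t>(n) * plane;
      for (size_t i = 0; i < plane; ++i) dst[i] = static_cast<double>(src[i]);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector X, NumericVector Wt,
                             NumericVector b, int pad) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch in convolution");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  const size_t rows = static_cast<size_t>(Ho) * Wo * N;
  arma::fmat A(rows, Cin), R(rows, Cout);
  R.zeros();
  for (int dwo = 0; dwo < kw; ++dwo) {
    for (int dho = 0; dho < kh; ++dho) {
      gather_offset(X.begin(), H, W, C, N, Ho, Wo, dho, dwo, pad, A);
      // W slice for this offset: Wk(ci, co) = Wt[dho, dwo, ci, co]
      arma::fmat Wk(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wk(ci, co) = static_cast<float>(
            Wt[dho + kh * (dwo + kw * (ci + static_cast<size_t>(Cin) * co))]);
      R += A * Wk;
    }
  }
  for (int co = 0; co < Cout; ++co) R.col(co) += static_cast<float>(b[co]);
  NumericVector Y(static_cast<R_xlen_t>(rows) * Cout);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  rows_to_y(R, Y, Ho, Wo, Cout, N);
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector X, NumericVector Wt, NumericVector dY,
                    int pad) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dWt(static_cast<R_xlen_t>(kh) * kw * Cin * Cout);
  dWt.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);

  const size_t rows = static_cast<size_t>(Ho) * Wo * N;
  arma::fmat G(rows, Cout);
  y_to_rows(dY, Ho, Wo, Cout, N, G);
  // db in double (a straight sum costs nothing extra in precision)
  for (int co = 0; co < Cout; ++co) {
    const double* src = dY.begin();
    double acc = 0;
    const size_t plane = static_cast<size_t>(Ho) * Wo;
    for (int n = 0; n < N; ++n) {
      const double* p0 = src + (static_cast<size_t>(n) * Cout + co) * plane;
      for (size_t i = 0; i < plane; ++i) acc += p0[i];
    }
    db[co] = acc;
  }

  arma::fmat A(rows, Cin);
  for (int dwo = 0; dwo < kw; ++dwo) {
    for (int dho = 0; dho < kh; ++dho) {
      gather_offset(X.begin(), H, W, C, N, Ho, Wo, dho, dwo, pad, A);
      arma::fmat dWk = A.t() * G;  // Cin x Cout
      arma::fmat Wk(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci) {
          const size_t wi = dho + kh * (dwo + kw * (ci + static_cast<size_t>(Cin) * co));
          dWt[wi] = static_cast<double>(dWk(ci, co));
          Wk(ci, co) = static_cast<float>(Wt[wi]);
        }
      arma::fmat dA = G * Wk.t();  // rows x Cin
      scatter_offset(dA, dX.begin(), H, W, C, N, Ho, Wo, dho, dwo, pad);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

// ---------------------------------------------------------------------------
// In-place SGDM update: v <- momentum*v - lr*g; p <- p + v. The caller
// guarantees p and v are not aliased elsewhere.
// [[Rcpp::export]]
void cpp_sgdm_step(NumericVector p, NumericVector g, NumericVector v,
                   double lr, double momentum) {
  const R_xlen_t n = p.size();
  if (g.size() != n || v.size() != n) stop("parameter/gradient shape mismatch");
  double* pp = p.begin();
  double* gp = g.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    vp[i] = momentum * vp[i] - lr * gp[i];
    pp[i] += vp[i];
  }
}

// ---------------------------------------------------------------------------
// Max pooling, square window k, stride s, no padding.
// Returns the pooled map and the argmax (1-based linear index into the
// (H, W) plane) used for gradient routing.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector X, int k, int s) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1;
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");

  NumericVector Y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector A(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  A.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = X.begin() + static_cast<size_t>(n) * H * W * C +
                            static_cast<size_t>(c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * s, w0 = wo * s;
          double best = plane[h0 + H * w0];
          int arg = h0 + H * w0;
          for (int dw = 0; dw < k; ++dw) {
            const double* colp = plane + static_cast<size_t>(w0 + dw) * H;
            for (int dh = 0; dh < k; ++dh) {
              if (colp[h0 + dh] > best) {
                best = colp[h0 + dh];
                arg = h0 + dh + H * (w0 + dw);
              }
            }
          }
          // column-major output index: ho + Ho*(wo + Wo*(c + C*n))
          const size_t oi = static_cast<size_t>(ho) +
                            static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * (c + static_cast<size_t>(C) * n));
          Y[oi] = best;
          A[oi] = arg + 1;
          (void)o;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector A, NumericVector dY,
                              IntegerVector in_dim) {
  IntegerVector dd = dY.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dX.begin() + static_cast<size_t>(n) * H * W * C +
                      static_cast<size_t>(c) * H * W;
      const size_t base = static_cast<size_t>(Ho) * Wo * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < static_cast<size_t>(Ho) * Wo; ++i) {
        plane[A[base + i] - 1] += dY[base + i];
      }
    }
  }
  return dX;
}
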