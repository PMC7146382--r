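// Convolutional autoencoder compute core.
//
// Activations live on zero-padded canvases: a layer with C channels over an
// S-sample chunk of H x W images is an (S*(H+2)*(W+2)) x C single-precision
// matrix, flattened row-major within each padded image (index = s*Hp*Wp +
// y*Wp + x).  A 3x3 'same' convolution then decomposes into nine BLAS sgemm
// calls on contiguous row bands of that matrix, one per kernel tap, with no
// im2col materialisation.  Pixels written outside the interior are garbage
// and are re-zeroed after each layer, which preserves zero-padding
// semantics exactly.
//
// Master weights are double precision on the R side; compute is float.
// Everything is deterministic for a fixed input on a fixed BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb, const float *beta,
                       float *c, const int *ldc);

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float *A, int lda, const float *B, int ldb,
                         float beta, float *C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

enum { KIND_CONV = 1, KIND_POOL = 2, KIND_UP = 3 };
enum { ACT_NONE = 0, ACT_RELU = 1, ACT_SIGMOID = 2 };
enum { LOSS_MSE = 1, LOSS_BCE = 2 };

// ---- canvas helpers -------------------------------------------------------

// zero the 1-pixel border of every sample's padded canvas
static void zero_pads(fmat &A, int S, int H, int W) {
  const int Hp = H + 2, Wp = W + 2, per = Hp * Wp;
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    float *p = A.colptr(c);
    for (int s = 0; s < S; ++s) {
      float *q = p + (size_t)s * per;
      std::memset(q, 0, sizeof(float) * Wp);                // top row
      std::memset(q + (size_t)(Hp - 1) * Wp, 0, sizeof(float) * Wp);
      for (int y = 1; y < Hp - 1; ++y) {                    // side columns
        q[(size_t)y * Wp] = 0.0f;
        q[(size_t)y * Wp + Wp - 1] = 0.0f;
      }
    }
  }
}

// embed samples [s0, s0+S) of an R array x[H,W,C,N] into a padded canvas
static fmat embed(const double *x, int H, int W, int C, int s0, int S) {
  const int Hp = H + 2, Wp = W + 2;
  fmat A((size_t)S * Hp * Wp, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float *dst = A.colptr(c);
    for (int s = 0; s < S; ++s) {
      const double *src = x + (size_t)H * W * (c + (size_t)C * (s0 + s));
      for (int w = 0; w < W; ++w) {
        const double *col = src + (size_t)H * w;
        float *d = dst + (size_t)s * Hp * Wp + Wp + (w + 1);
        for (int h = 0; h < H; ++h) d[(size_t)h * Wp] = (float)col[h];
      }
    }
  }
  return A;
}

// copy canvas interior back into an R array out[H,W,C,N] at samples s0..
static void extract(const fmat &A, double *out, int H, int W, int C,
                    int Ctot, int s0, int S) {
  const int Hp = H + 2, Wp = W + 2;
  for (int c = 0; c < C; ++c) {
    const float *src = A.colptr(c);
    for (int s = 0; s < S; ++s) {
      double *dst = out + (size_t)H * W * (c + (size_t)Ctot * (s0 + s));
      for (int w = 0; w < W; ++w) {
        const float *d = src + (size_t)s * Hp * Wp + Wp + (w + 1);
        double *col = dst + (size_t)H * w;
        for (int h = 0; h < H; ++h) col[h] = (double)d[(size_t)h * Wp];
      }
    }
  }
}

// ---- per-layer primitives -------------------------------------------------

// split an R weight array (3,3,cin,cout) into nine cin x cout tap matrices;
// tap t = ky + 3*kx maps to spatial offset (dy, dx) = (ky-1, kx-1)
static std::vector<fmat> split_taps(const double *w, int cin, int cout) {
  std::vector<fmat> Wk(9);
  for (int t = 0; t < 9; ++t) {
    Wk[t].set_size(cin, cout);
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        Wk[t](ci, co) = (float)w[t + 9 * (ci + (size_t)cin * co)];
  }
  return Wk;
}

static fmat conv_forward(const fmat &A, const std::vector<fmat> &Wk,
                         const frowvec &b, int S, int H, int W, int act) {
  const int Wp = W + 2;
  const int R = (int)A.n_rows, cin = (int)A.n_cols, cout = (int)Wk[0].n_cols;
  fmat Z(R, cout);
  Z.each_row() = b;
  const int lo = Wp + 1, hi = R - Wp - 2, m = hi - lo + 1;
  for (int t = 0; t < 9; ++t) {
    const int o = (t % 3 - 1) * Wp + (t / 3 - 1);
    sgemm('N', 'N', m, cout, cin, 1.0f, A.memptr() + lo + o, R,
          Wk[t].memptr(), cin, 1.0f, Z.memptr() + lo, R);
  }
  if (act == ACT_RELU) {
    Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  } else if (act == ACT_SIGMOID) {
    Z.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  }
  zero_pads(Z, S, H, W);
  return Z;
}

static fmat pool_forward(const fmat &A, int S, int H, int W,
                         arma::umat &argmax) {
  const int Hp = H + 2, Wp = W + 2, H2 = H / 2, W2 = W / 2;
  const int H2p = H2 + 2, W2p = W2 + 2;
  const int C = (int)A.n_cols;
  fmat Z((size_t)S * H2p * W2p, C, arma::fill::zeros);
  argmax.zeros((size_t)S * H2p * W2p, C);
  for (int c = 0; c < C; ++c) {
    const float *a = A.colptr(c);
    float *z = Z.colptr(c);
    arma::uword *am = argmax.colptr(c);
    for (int s = 0; s < S; ++s) {
      for (int y2 = 0; y2 < H2; ++y2) {
        for (int x2 = 0; x2 < W2; ++x2) {
          size_t i00 = (size_t)s * Hp * Wp + (size_t)(2 * y2 + 1) * Wp +
                       (2 * x2 + 1);
          size_t idx[4] = {i00, i00 + 1, i00 + Wp, i00 + Wp + 1};
          size_t best = idx[0];
          float bv = a[idx[0]];
          for (int j = 1; j < 4; ++j)
            if (a[idx[j]] > bv) { bv = a[idx[j]]; best = idx[j]; }
          size_t io = (size_t)s * H2p * W2p + (size_t)(y2 + 1) * W2p +
                      (x2 + 1);
          z[io] = bv;
          am[io] = best;
        }
      }
    }
  }
  return Z;
}

static fmat up_forward(const fmat &A, int S, int H, int W) {
  const int Hp = H + 2, Wp = W + 2, H2 = H * 2, W2 = W * 2;
  const int H2p = H2 + 2, W2p = W2 + 2;
  const int C = (int)A.n_cols;
  fmat Z((size_t)S * H2p * W2p, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float *a = A.colptr(c);
    float *z = Z.colptr(c);
    for (int s = 0; s < S; ++s) {
      for (int y = 0; y < H; ++y) {
        for (int x = 0; x < W; ++x) {
          float v = a[(size_t)s * Hp * Wp + (size_t)(y + 1) * Wp + (x + 1)];
          size_t o = (size_t)s * H2p * W2p + (size_t)(2 * y + 1) * W2p +
                     (2 * x + 1);
          z[o] = v;
          z[o + 1] = v;
          z[o + W2p] = v;
          z[o + W2p + 1] = v;
        }
      }
    }
  }
  return Z;
}

// ---- geometry -------------------------------------------------------------

struct Geom {
  std::vector<int> H, W, Cin, Cout;  // per layer, input side + output channels
};

static Geom layer_geometry(const IntegerVector &kind,
                           const IntegerVector &cout, int H0, int W0, int C0,
                           int from) {
  const int L = kind.size();
  Geom g;
  g.H.resize(L); g.W.resize(L); g.Cin.resize(L); g.Cout.resize(L);
  int H = H0, W = W0, C = C0;
  for (int l = from; l < L; ++l) {
    g.H[l] = H; g.W[l] = W; g.Cin[l] = C;
    if (kind[l] == KIND_CONV) {
      C = cout[l];
    } else if (kind[l] == KIND_POOL) {
      if (l >= from && (H % 2 || W % 2))
        stop("max-pooling requires even spatial dims, got %dx%d", H, W);
      H /= 2; W /= 2;
    } else {
      H *= 2; W *= 2;
    }
    g.Cout[l] = C;
  }
  return g;
}

// ---- forward --------------------------------------------------------------

// Run layers [from, upto] on x[H,W,C,N]; returns output array [H',W',C',N].
// [[Rcpp::export]]
NumericVector nc_forward(List weights, IntegerVector kind, IntegerVector cout,
                         IntegerVector act, NumericVector x, int from,
                         int upto, int chunk) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-d array [H,W,C,N]");
  const int H0 = xd[0], W0 = xd[1], C0 = xd[2], N = xd[3];
  const int L = kind.size();
  if (from < 0 || upto >= L || from > upto) stop("bad layer range");
  Geom g = layer_geometry(kind, cout, H0, W0, C0, from);
  if (g.Cin[from] != C0) stop("input has %d channels, layer expects %d", C0,
                              g.Cin[from]);
  if (g.H[from] != H0 || g.W[from] != W0)
    stop("input is %dx%d, layer expects %dx%d", H0, W0, g.H[from], g.W[from]);
  int Ho = H0, Wo = W0;
  for (int l = from; l <= upto; ++l) {
    if (kind[l] == KIND_POOL) { Ho /= 2; Wo /= 2; }
    else if (kind[l] == KIND_UP) { Ho *= 2; Wo *= 2; }
  }
  const int Co = g.Cout[upto];

  NumericVector out((size_t)Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  double *op = REAL(out);
  const double *xp = REAL(x);

  std::vector<std::vector<fmat> > Wtaps(L);
  std::vector<frowvec> bias(L);
  for (int l = from; l <= upto; ++l) {
    if (kind[l] != KIND_CONV) continue;
    List wl = weights[l];
    NumericVector Wv = wl["W"], bv = wl["b"];
    Wtaps[l] = split_taps(REAL(Wv), g.Cin[l], g.Cout[l]);
    bias[l].set_size(g.Cout[l]);
    for (int j = 0; j < g.Cout[l]; ++j) bias[l](j) = (float)bv[j];
  }

  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int S = std::min(chunk, N - s0);
    fmat A = embed(xp, H0, W0, C0, s0, S);
    int Hc = H0, Wc = W0;
    for (int l = from; l <= upto; ++l) {
      if (kind[l] == KIND_CONV) {
        A = conv_forward(A, Wtaps[l], bias[l], S, Hc, Wc, act[l]);
      } else if (kind[l] == KIND_POOL) {
        arma::umat am;
        A = pool_forward(A, S, Hc, Wc, am);
        Hc /= 2; Wc /= 2;
      } else {
        A = up_forward(A, S, Hc, Wc);
        Hc *= 2; Wc *= 2;
      }
    }
    extract(A, op, Ho, Wo, Co, Co, s0, S);
  }
  return out;
}

// ---- loss + gradient ------------------------------------------------------

// Mean loss over the whole batch and mean gradients for layers [from, L-1].
// y has the same H,W as the network output.  For BCE the final layer must be
// a sigmoid conv; the sigmoid/BCE gradient is fused for stability.
// [[Rcpp::export]]
List nc_grad(List weights, IntegerVector kind, IntegerVector cout,
             IntegerVector act, NumericVector x, NumericVector y,
             int loss_type, int from, int chunk) {
  IntegerVector xd = x.attr("dim"), yd = y.attr("dim");
  const int H0 = xd[0], W0 = xd[1], C0 = xd[2], N = xd[3];
  const int L = kind.size();
  Geom g = layer_geometry(kind, cout, H0, W0, C0, from);
  if (kind[L - 1] != KIND_CONV) stop("last layer must be a conv");
  const int Ho = g.H[L - 1], Wo = g.W[L - 1], Co = g.Cout[L - 1];
  if (yd[0] != Ho || yd[1] != Wo || yd[2] != Co || yd[3] != N)
    stop("target dims do not match network output");
  if (loss_type == LOSS_BCE && act[L - 1] != ACT_SIGMOID)
    stop("BCE loss requires a sigmoid output layer");

  const double norm = (double)N * Ho * Wo * Co;  // mean over all elements
  double loss_sum = 0.0;

  // gradient accumulators (double to sum across chunks safely)
  std::vector<arma::mat> dW(L);
  std::vector<arma::rowvec> db(L);
  for (int l = from; l < L; ++l)
    if (kind[l] == KIND_CONV) {
      dW[l].zeros(9 * (size_t)g.Cin[l], g.Cout[l]);
      db[l].zeros(g.Cout[l]);
    }

  const double *xp = REAL(x), *yp = REAL(y);

  // hoist weight conversion out of the chunk loop
  std::vector<std::vector<fmat> > Wtaps(L);
  std::vector<frowvec> bias(L);
  for (int l = from; l < L; ++l) {
    if (kind[l] != KIND_CONV) continue;
    List wl = weights[l];
    NumericVector Wv = wl["W"], bv = wl["b"];
    Wtaps[l] = split_taps(REAL(Wv), g.Cin[l], g.Cout[l]);
    bias[l].set_size(g.Cout[l]);
    for (int j = 0; j < g.Cout[l]; ++j) bias[l](j) = (float)bv[j];
  }

  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int S = std::min(chunk, N - s0);

    // forward, caching post-activation canvases
    std::vector<fmat> acts(L - from + 1);
    std::vector<arma::umat> argmax(L);
    acts[0] = embed(xp, H0, W0, C0, s0, S);
    {
      int Hc = H0, Wc = W0;
      for (int l = from; l < L; ++l) {
        if (kind[l] == KIND_CONV) {
          acts[l - from + 1] = conv_forward(acts[l - from], Wtaps[l],
                                            bias[l], S, Hc, Wc, act[l]);
        } else if (kind[l] == KIND_POOL) {
          acts[l - from + 1] = pool_forward(acts[l - from], S, Hc, Wc,
                                            argmax[l]);
          Hc /= 2; Wc /= 2;
        } else {
          acts[l - from + 1] = up_forward(acts[l - from], S, Hc, Wc);
          Hc *= 2; Wc *= 2;
        }
      }
    }

    // loss and seed gradient on the output canvas
    const fmat &O = acts[L - from];
    const int Hop = Ho + 2, Wop = Wo + 2;
    fmat dcur((size_t)S * Hop * Wop, Co, arma::fill::zeros);
    bool seed_is_preact = false;
    for (int c = 0; c < Co; ++c) {
      const float *o = O.colptr(c);
      float *d = dcur.colptr(c);
      for (int s = 0; s < S; ++s) {
        const double *yc =
            yp + (size_t)Ho * Wo * (c + (size_t)Co * (s0 + s));
        for (int w = 0; w < Wo; ++w) {
          for (int h = 0; h < Ho; ++h) {
            size_t i = (size_t)s * Hop * Wop + (size_t)(h + 1) * Wop +
                       (w + 1);
            double ov = o[i], yv = yc[h + (size_t)Ho * w];
            if (loss_type == LOSS_MSE) {
              double e = ov - yv;
              loss_sum += e * e;
              d[i] = (float)(2.0 * e / norm);
            } else {
              double p = std::min(std::max(ov, 1e-7), 1.0 - 1e-7);
              loss_sum += -(yv * std::log(p) + (1.0 - yv) * std::log(1.0 - p));
              d[i] = (float)((ov - yv) / norm);  // fused sigmoid+BCE
            }
          }
        }
      }
    }
    if (loss_type == LOSS_BCE) seed_is_preact = true;

    // backward
    int Hc = Ho, Wc = Wo;  // spatial dims at the *output* of layer l
    for (int l = L - 1; l >= from; --l) {
      const fmat &Aout = acts[l - from + 1];
      const fmat &Ain = acts[l - from];
      if (kind[l] == KIND_CONV) {
        fmat dpre;
        if (l == L - 1 && seed_is_preact) {
          dpre = std::move(dcur);
        } else {
          dpre = std::move(dcur);
          if (act[l] == ACT_RELU) {
            const float *ao = Aout.memptr();
            float *dp = dpre.memptr();
            const size_t ne = dpre.n_elem;
            for (size_t i = 0; i < ne; ++i)
              if (ao[i] <= 0.0f) dp[i] = 0.0f;
          } else if (act[l] == ACT_SIGMOID) {
            const float *ao = Aout.memptr();
            float *dp = dpre.memptr();
            const size_t ne = dpre.n_elem;
            for (size_t i = 0; i < ne; ++i) dp[i] *= ao[i] * (1.0f - ao[i]);
          }
        }
        const int Wp = Wc + 2;
        const int R = (int)dpre.n_rows;
        const int lo = Wp + 1, hi = R - Wp - 2, m = hi - lo + 1;
        const int cin = g.Cin[l], co = g.Cout[l];
        // bias gradient
        db[l] += arma::conv_to<arma::rowvec>::from(arma::sum(dpre, 0));
        // weight gradients: dWk = Ain(band+o)^T * dpre(band)
        fmat dwk(cin, co);
        for (int t = 0; t < 9; ++t) {
          const int o = (t % 3 - 1) * Wp + (t / 3 - 1);
          sgemm('T', 'N', cin, co, m, 1.0f, Ain.memptr() + lo + o,
                (int)Ain.n_rows, dpre.memptr() + lo, R, 0.0f, dwk.memptr(),
                cin);
          for (int cj = 0; cj < co; ++cj)
            for (int ci = 0; ci < cin; ++ci)
              dW[l](t + (size_t)9 * ci, cj) += (double)dwk(ci, cj);
        }
        if (l > from) {
          fmat dprev(Ain.n_rows, cin, arma::fill::zeros);
          for (int t = 0; t < 9; ++t) {
            const int o = (t % 3 - 1) * Wp + (t / 3 - 1);
            sgemm('N', 'T', m, cin, co, 1.0f, dpre.memptr() + lo, R,
                  Wtaps[l][t].memptr(), cin, 1.0f, dprev.memptr() + lo + o,
                  (int)dprev.n_rows);
          }
          zero_pads(dprev, S, Hc, Wc);
          dcur = std::move(dprev);
        }
      } else if (kind[l] == KIND_POOL) {
        // output dims Hc x Wc, input dims 2Hc x 2Wc
        const int Hi = Hc * 2, Wi = Wc * 2;
        fmat dprev(Ain.n_rows, Aout.n_cols, arma::fill::zeros);
        const int Hop2 = Hc + 2, Wop2 = Wc + 2;
        for (arma::uword c = 0; c < Aout.n_cols; ++c) {
          const float *d = dcur.colptr(c);
          const arma::uword *am = argmax[l].colptr(c);
          float *dp = dprev.colptr(c);
          for (int s = 0; s < S; ++s)
            for (int yv = 0; yv < Hc; ++yv)
              for (int xv = 0; xv < Wc; ++xv) {
                size_t io = (size_t)s * Hop2 * Wop2 +
                            (size_t)(yv + 1) * Wop2 + (xv + 1);
                dp[am[io]] += d[io];
              }
        }
        zero_pads(dprev, S, Hi, Wi);  // argmax never points at padding
        dcur = std::move(dprev);
        Hc = Hi; Wc = Wi;
      } else {  // upsample: input dims Hc/2 x Wc/2
        const int Hi = Hc / 2, Wi = Wc / 2;
        const int Hip = Hi + 2, Wip = Wi + 2, Hop2 = Hc + 2, Wop2 = Wc + 2;
        fmat dprev(Ain.n_rows, Aout.n_cols, arma::fill::zeros);
        for (arma::uword c = 0; c < Aout.n_cols; ++c) {
          const float *d = dcur.colptr(c);
          float *dp = dprev.colptr(c);
          for (int s = 0; s < S; ++s)
            for (int yv = 0; yv < Hi; ++yv)
              for (int xv = 0; xv < Wi; ++xv) {
                size_t o = (size_t)s * Hop2 * Wop2 +
                           (size_t)(2 * yv + 1) * Wop2 + (2 * xv + 1);
                dp[(size_t)s * Hip * Wip + (size_t)(yv + 1) * Wip +
                   (xv + 1)] = d[o] + d[o + 1] + d[o + Wop2] +
                               d[o + Wop2 + 1];
              }
        }
        dcur = std::move(dprev);
        Hc = Hi; Wc = Wi;
      }
    }
  }

  // package gradients back into R arrays (3,3,cin,cout)
  List grads(L);
  for (int l = from; l < L; ++l) {
    if (kind[l] != KIND_CONV) continue;
    const int cin = g.Cin[l], co = g.Cout[l];
    NumericVector gw((size_t)9 * cin * co);
    gw.attr("dim") = IntegerVector::create(3, 3, cin, co);
    double *p = REAL(gw);
    for (int cj = 0; cj < co; ++cj)
      for (int ci = 0; ci < cin; ++ci)
        for (int t = 0; t < 9; ++t)
          p[t + 9 * (ci + (size_t)cin * cj)] = dW[l](t + (size_t)9 * ci, cj);
    NumericVector gb(co);
    for (int j = 0; j < co; ++j) gb[j] = db[l](j);
    grads[l] = List::create(Named("W") = gw, Named("b") = gb);
  }

  return List::create(Named("loss") = loss_sum / norm,
                      Named("grads") = grads);
}
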