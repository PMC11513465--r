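// 3D convolution primitives (stride 1, zero padding, "same" output size)
// used by the central difference convolution operator and the network.
//
// Array layout follows R column-major conventions throughout:
//   feature maps  x : dim (T, H, W, C)   -> element (t,h,w,c) at
//                                           t + T*(h + H*(w + W*c))
//   kernels       w : dim (kt, kh, kw, Cin, Cout)
//
// Implementation: the input is copied once into a zero-padded buffer of
// dim (T+2rt, H+2rh, W+2rw, C) viewed as a Q x C matrix (Q = padded grid
// size). In that common layout a kernel tap offset (dt, dh, dw) becomes a
// constant shift s of the flat row index, so each tap contributes one
// rank-C update
//   out[q, ] += xpad[q + s, ] %*% W_tap          (W_tap: Cin x Cout)
// realized as a single BLAS dgemm on row-offset submatrix views (leading
// dimension Q). Halo rows absorb the shifts; only the interior is read
// back. The backward pass reuses the same alignment with transposed
// weights / inputs. This avoids materializing im2col patch matrices.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array (T, H, W, C)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static void get_dims5(const NumericVector& w, int* d) {
  IntegerVector dim = w.attr("dim");
  if (dim.size() != 5) stop("expected a 5-d kernel array (kt, kh, kw, Cin, Cout)");
  for (int i = 0; i < 5; ++i) d[i] = dim[i];
}

// copy a (T,H,W,C) array into the interior of a zeroed padded (Q x C) buffer
static std::vector<double> padGrid(const double* x, int T, int H, int W, int C,
                                   int rt, int rh, int rw) {
  const int Tp = T + 2 * rt, Hp = H + 2 * rh, Wp = W + 2 * rw;
  const size_t Q = (size_t)Tp * Hp * Wp;
  std::vector<double> xp(Q * C, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* src = x + (size_t)c * T * H * W;
    double* dstc = xp.data() + (size_t)c * Q;
    for (int w2 = 0; w2 < W; ++w2)
      for (int h2 = 0; h2 < H; ++h2) {
        const double* s = src + (size_t)T * (h2 + (size_t)H * w2);
        double* d = dstc + (size_t)rt +
          (size_t)Tp * ((h2 + rh) + (size_t)Hp * (w2 + rw));
        std::memcpy(d, s, sizeof(double) * T);
      }
  }
  return xp;
}

// crop the interior of a padded (Q x C) buffer back to a (T,H,W,C) array
static void cropGrid(const std::vector<double>& xp, double* out,
                     int T, int H, int W, int C, int rt, int rh, int rw) {
  const int Tp = T + 2 * rt, Hp = H + 2 * rh, Wp = W + 2 * rw;
  const size_t Q = (size_t)Tp * Hp * Wp;
  for (int c = 0; c < C; ++c) {
    const double* srcc = xp.data() + (size_t)c * Q;
    double* dst = out + (size_t)c * T * H * W;
    for (int w2 = 0; w2 < W; ++w2)
      for (int h2 = 0; h2 < H; ++h2) {
        const double* s = srcc + (size_t)rt +
          (size_t)Tp * ((h2 + rh) + (size_t)Hp * (w2 + rw));
        double* d = dst + (size_t)T * (h2 + (size_t)H * w2);
        std::memcpy(d, s, sizeof(double) * T);
      }
  }
}

// gather the (Cin x Cout) weight slice of one kernel tap
static void tapWeights(const double* w, int taps, int tap, int Cin, int Cout,
                       std::vector<double>& wtap) {
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      wtap[ci + (size_t)Cin * co] =
        w[tap + (size_t)taps * (ci + (size_t)Cin * co)];
}

// [[Rcpp::export(name = ".cppConv3dForward")]]
NumericVector cppConv3dForward(NumericVector x, NumericVector w,
                               NumericVector bias) {
  int xd[4], wd[5];
  get_dims4(x, xd);
  get_dims5(w, wd);
  const int T = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], Cout = wd[4];
  if (wd[3] != Cin) stop("input channels do not match kernel");
  if (bias.size() != Cout) stop("bias length must equal output channels");
  const int rt = kt / 2, rh = kh / 2, rw = kw / 2;
  const int Tp = T + 2 * rt, Hp = H + 2 * rh, Wp = W + 2 * rw;
  const int Q = Tp * Hp * Wp;
  const int taps = kt * kh * kw;

  std::vector<double> xp = padGrid(x.begin(), T, H, W, Cin, rt, rh, rw);
  std::vector<double> outp((size_t)Q * Cout, 0.0);
  std::vector<double> wtap((size_t)Cin * Cout);
  const double one = 1.0;

  for (int dw2 = 0; dw2 < kw; ++dw2)
    for (int dh = 0; dh < kh; ++dh)
      for (int dt = 0; dt < kt; ++dt) {
        const int tap = dt + kt * (dh + kh * dw2);
        tapWeights(w.begin(), taps, tap, Cin, Cout, wtap);
        const int s = (dt - rt) + Tp * ((dh - rh) + Hp * (dw2 - rw));
        const int M = Q - std::abs(s);
        const double* A = xp.data() + std::max(0, s);
        double* C = outp.data() + std::max(0, -s);
        F77_CALL(dgemm)("N", "N", &M, &Cout, &Cin, &one, A, &Q,
                        wtap.data(), &Cin, &one, C, &Q FCONE FCONE);
      }

  NumericVector res((size_t)T * H * W * Cout);
  cropGrid(outp, res.begin(), T, H, W, Cout, rt, rh, rw);
  double* rp = res.begin();
  const size_t P = (size_t)T * H * W;
  for (int co = 0; co < Cout; ++co) {
    const double b = bias[co];
    for (size_t i = 0; i < P; ++i) rp[(size_t)co * P + i] += b;
  }
  res.attr("dim") = IntegerVector::create(T, H, W, Cout);
  return res;
}

// [[Rcpp::export(name = ".cppConv3dBackward")]]
List cppConv3dBackward(NumericVector x, NumericVector w, NumericVector dout,
                       bool need_dx = true) {
  int xd[4], wd[5], od[4];
  get_dims4(x, xd);
  get_dims5(w, wd);
  get_dims4(dout, od);
  const int T = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], Cout = wd[4];
  if (wd[3] != Cin) stop("input channels do not match kernel");
  if (od[0] != T || od[1] != H || od[2] != W || od[3] != Cout)
    stop("gradient shape does not match");
  const int rt = kt / 2, rh = kh / 2, rw = kw / 2;
  const int Tp = T + 2 * rt, Hp = H + 2 * rh, Wp = W + 2 * rw;
  const int Q = Tp * Hp * Wp;
  const int taps = kt * kh * kw;
  const size_t P = (size_t)T * H * W;

  std::vector<double> xp = padGrid(x.begin(), T, H, W, Cin, rt, rh, rw);
  std::vector<double> dop = padGrid(dout.begin(), T, H, W, Cout, rt, rh, rw);
  std::vector<double> dxp(need_dx ? (size_t)Q * Cin : 0, 0.0);
  std::vector<double> wtap((size_t)Cin * Cout);
  std::vector<double> gtap((size_t)Cin * Cout);
  NumericVector dw((size_t)taps * Cin * Cout);
  const double one = 1.0, zero = 0.0;

  for (int dw2 = 0; dw2 < kw; ++dw2)
    for (int dh = 0; dh < kh; ++dh)
      for (int dt = 0; dt < kt; ++dt) {
        const int tap = dt + kt * (dh + kh * dw2);
        const int s = (dt - rt) + Tp * ((dh - rh) + Hp * (dw2 - rw));
        const int M = Q - std::abs(s);
        const double* Axp = xp.data() + std::max(0, s);
        const double* Ado = dop.data() + std::max(0, -s);
        // dW_tap (Cin x Cout) = xp_shifted' * dout
        F77_CALL(dgemm)("T", "N", &Cin, &Cout, &M, &one, Axp, &Q,
                        Ado, &Q, &zero, gtap.data(), &Cin FCONE FCONE);
        double* dwp = dw.begin();
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dwp[tap + (size_t)taps * (ci + (size_t)Cin * co)] =
              gtap[ci + (size_t)Cin * co];
        if (need_dx) {
          // dx_shifted += dout * W_tap'
          tapWeights(w.begin(), taps, tap, Cin, Cout, wtap);
          double* Cdx = dxp.data() + std::max(0, s);
          F77_CALL(dgemm)("N", "T", &M, &Cin, &Cout, &one, Ado, &Q,
                          wtap.data(), &Cin, &one, Cdx, &Q FCONE FCONE);
        }
      }

  NumericVector dx(need_dx ? (size_t)P * Cin : 0);
  if (need_dx) {
    cropGrid(dxp, dx.begin(), T, H, W, Cin, rt, rh, rw);
    dx.attr("dim") = IntegerVector::create(T, H, W, Cin);
  }
  dw.attr("dim") = IntegerVector::create(kt, kh, kw, Cin, Cout);

  NumericVector db(Cout);
  const double* dp = dout.begin();
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (size_t i = 0; i < P; ++i) s += dp[(size_t)co * P + i];
    db[co] = s;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
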