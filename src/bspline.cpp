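#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hot loops work on raw column-major buffers (NumericMatrix::operator()
// is an order of magnitude slower than pointer indexing here).

// Cubic B-spline basis and derivative.  Support is |t| < 2.
static inline double b3(double t) {
  double a = std::fabs(t);
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  if (a < 2.0) { double u = 2.0 - a; return u * u * u / 6.0; }
  return 0.0;
}
static inline double db3(double t) {
  double a = std::fabs(t), s = (t < 0.0) ? -1.0 : 1.0;
  if (a < 1.0) return s * (-12.0 * a + 9.0 * a * a) / 6.0;
  if (a < 2.0) { double u = 2.0 - a; return -s * u * u / 2.0; }
  return 0.0;
}

// Basis weights at coordinate x (spacing s): 4 column indices into a grid
// whose col c corresponds to knot k = c - 1, and 4 weights/derivatives.
// Out-of-grid knots get weight 0.
static inline void basis1d(double x, double s, int nc,
                           int idx[4], double w[4], double dw[4]) {
  double t = x / s;
  int i0 = (int)std::floor(t);
  for (int m = 0; m < 4; ++m) {
    int k = i0 - 1 + m;
    idx[m] = k + 1;
    if (idx[m] < 0 || idx[m] >= nc) { w[m] = 0.0; dw[m] = 0.0; idx[m] = 0; continue; }
    w[m]  = b3(t - k);
    dw[m] = db3(t - k) / s;
  }
}

struct BasisTables {
  std::vector<int> ix, iy;
  std::vector<double> wx, wy, dwx, dwy;
  BasisTables(int W, int H, double sx, double sy, int nk, int nl)
      : ix(4 * W), iy(4 * H), wx(4 * W), wy(4 * H), dwx(4 * W), dwy(4 * H) {
    for (int x = 0; x < W; ++x) basis1d((double)x, sx, nk, &ix[4*x], &wx[4*x], &dwx[4*x]);
    for (int y = 0; y < H; ++y) basis1d((double)y, sy, nl, &iy[4*y], &wy[4*y], &dwy[4*y]);
  }
};

// Evaluate the field at arbitrary points.  cx/cy are (L+3) x (K+3)
// coefficient matrices (rows follow y, cols follow x).
// [[Rcpp::export]]
NumericMatrix cpp_field_eval_points(NumericMatrix cx, NumericMatrix cy,
                                    double sx, double sy,
                                    NumericVector px, NumericVector py) {
  int n = px.size(), nk = cx.ncol(), nl = cx.nrow();
  const double *CX = cx.begin(), *CY = cy.begin();
  NumericMatrix out(n, 2);
  int ix[4], iy[4];
  double wx[4], wy[4], d[4];
  for (int i = 0; i < n; ++i) {
    basis1d(px[i], sx, nk, ix, wx, d);
    basis1d(py[i], sy, nl, iy, wy, d);
    double gx = 0.0, gy = 0.0;
    for (int b = 0; b < 4; ++b) {
      if (wy[b] == 0.0) continue;
      for (int a = 0; a < 4; ++a) {
        double w = wx[a] * wy[b];
        if (w == 0.0) continue;
        size_t o = (size_t)ix[a] * nl + iy[b];
        gx += CX[o] * w;
        gy += CY[o] * w;
      }
    }
    out(i, 0) = gx; out(i, 1) = gy;
  }
  return out;
}

// Field evaluated on the full pixel grid; returns H x W matrices gx, gy.
// [[Rcpp::export]]
List cpp_field_grid(NumericMatrix cx, NumericMatrix cy,
                    double sx, double sy, int W, int H) {
  int nk = cx.ncol(), nl = cx.nrow();
  const double *CX = cx.begin(), *CY = cy.begin();
  NumericMatrix gx(H, W), gy(H, W);
  double *GX = gx.begin(), *GY = gy.begin();
  BasisTables T(W, H, sx, sy, nk, nl);
  for (int x = 0; x < W; ++x) {
    const int *ixp = &T.ix[4*x]; const double *wxp = &T.wx[4*x];
    for (int y = 0; y < H; ++y) {
      const int *iyp = &T.iy[4*y]; const double *wyp = &T.wy[4*y];
      double vx = 0.0, vy = 0.0;
      for (int b = 0; b < 4; ++b) {
        double wyb = wyp[b]; if (wyb == 0.0) continue;
        int r = iyp[b];
        for (int a = 0; a < 4; ++a) {
          double w = wxp[a] * wyb; if (w == 0.0) continue;
          size_t o = (size_t)ixp[a] * nl + r;
          vx += CX[o] * w;
          vy += CY[o] * w;
        }
      }
      GX[(size_t)x * H + y] = vx; GY[(size_t)x * H + y] = vy;
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Bilinear sample on a raw H x W column-major buffer; OOB -> 0.
static inline double sample_bilinear(const double *img, int W, int H,
                                     double x, double y,
                                     bool &ok, double &dx, double &dy) {
  const double eps = 1e-9; // tolerate roundoff at the domain boundary
  if (x < -eps || y < -eps || x > W - 1.0 + eps || y > H - 1.0 + eps) {
    ok = false; dx = dy = 0.0; return 0.0;
  }
  ok = true;
  if (x < 0.0) x = 0.0; if (x > W - 1.0) x = W - 1.0;
  if (y < 0.0) y = 0.0; if (y > H - 1.0) y = H - 1.0;
  // snap coordinates within roundoff of a pixel center: keeps warps by
  // identity / integer-translation fields bit-exact
  double xr = std::round(x), yr = std::round(y);
  if (std::fabs(x - xr) < 1e-9) x = xr;
  if (std::fabs(y - yr) < 1e-9) y = yr;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > W - 2) x0 = W - 2; if (x0 < 0) x0 = 0;
  if (y0 > H - 2) y0 = H - 2; if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  const double *c0 = img + (size_t)x0 * H + y0;
  const double *c1 = c0 + H;
  double v00 = c0[0], v10 = c0[1], v01 = c1[0], v11 = c1[1];
  dx = (1 - fy) * (v01 - v00) + fy * (v11 - v10);
  dy = (1 - fx) * (v10 - v00) + fx * (v11 - v01);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Backward warp of img by sampling maps gx, gy (same shape as output).
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix gx, NumericMatrix gy) {
  int H = gx.nrow(), W = gx.ncol();
  int sH = img.nrow(), sW = img.ncol();
  const double *I = img.begin(), *GX = gx.begin(), *GY = gy.begin();
  NumericMatrix out(H, W);
  double *O = out.begin();
  bool ok; double dx, dy;
  for (size_t i = 0; i < (size_t)W * H; ++i)
    O[i] = sample_bilinear(I, sW, sH, GX[i], GY[i], ok, dx, dy);
  return out;
}

// Mean Euclidean displacement ||g(x,y) - (x,y)|| over the pixel grid.
// [[Rcpp::export]]
double cpp_mean_deformation(NumericMatrix cx, NumericMatrix cy,
                            double sx, double sy, int W, int H) {
  int nk = cx.ncol(), nl = cx.nrow();
  const double *CX = cx.begin(), *CY = cy.begin();
  BasisTables T(W, H, sx, sy, nk, nl);
  double acc = 0.0;
  for (int x = 0; x < W; ++x) {
    const int *ixp = &T.ix[4*x]; const double *wxp = &T.wx[4*x];
    for (int y = 0; y < H; ++y) {
      const int *iyp = &T.iy[4*y]; const double *wyp = &T.wy[4*y];
      double vx = 0.0, vy = 0.0;
      for (int b = 0; b < 4; ++b) {
        double wyb = wyp[b]; if (wyb == 0.0) continue;
        int r = iyp[b];
        for (int a = 0; a < 4; ++a) {
          double w = wxp[a] * wyb; if (w == 0.0) continue;
          size_t o = (size_t)ixp[a] * nl + r;
          vx += CX[o] * w;
          vy += CY[o] * w;
        }
      }
      double ux = vx - x, uy = vy - y;
      if (std::fabs(ux) < 1e-9) ux = 0.0;  // identity fields measure exactly 0
      if (std::fabs(uy) < 1e-9) uy = 0.0;
      acc += std::sqrt(ux * ux + uy * uy);
    }
  }
  return acc / ((double)W * H);
}

// Image similarity energy: mean squared difference between warp(src, g) and
// tgt over in-domain pixels, plus its gradient w.r.t. the coefficients.
// [[Rcpp::export]]
List cpp_eimg_grad(NumericMatrix src, NumericMatrix tgt,
                   NumericMatrix cx, NumericMatrix cy,
                   double sx, double sy, bool want_grad) {
  int H = tgt.nrow(), W = tgt.ncol();
  int sH = src.nrow(), sW = src.ncol();
  int nk = cx.ncol(), nl = cx.nrow();
  const double *CX = cx.begin(), *CY = cy.begin();
  const double *S = src.begin(), *Tg = tgt.begin();
  NumericMatrix gx(nl, nk), gy(nl, nk);
  double *GX = gx.begin(), *GY = gy.begin();
  BasisTables T(W, H, sx, sy, nk, nl);
  double E = 0.0; long n_in = 0;
  bool ok; double dIx, dIy;
  for (int x = 0; x < W; ++x) {
    const int *ixp = &T.ix[4*x]; const double *wxp = &T.wx[4*x];
    for (int y = 0; y < H; ++y) {
      const int *iyp = &T.iy[4*y]; const double *wyp = &T.wy[4*y];
      double px = 0.0, py = 0.0;
      for (int b = 0; b < 4; ++b) {
        double wyb = wyp[b]; if (wyb == 0.0) continue;
        int r = iyp[b];
        for (int a = 0; a < 4; ++a) {
          double w = wxp[a] * wyb; if (w == 0.0) continue;
          size_t o = (size_t)ixp[a] * nl + r;
          px += CX[o] * w;
          py += CY[o] * w;
        }
      }
      double v = sample_bilinear(S, sW, sH, px, py, ok, dIx, dIy);
      if (!ok) continue;
      double diff = v - Tg[(size_t)x * H + y];
      E += diff * diff;
      ++n_in;
      if (want_grad) {
        double cfx = 2.0 * diff * dIx, cfy = 2.0 * diff * dIy;
        for (int b = 0; b < 4; ++b) {
          double wyb = wyp[b]; if (wyb == 0.0) continue;
          int r = iyp[b];
          for (int a = 0; a < 4; ++a) {
            double w = wxp[a] * wyb; if (w == 0.0) continue;
            size_t o = (size_t)ixp[a] * nl + r;
            GX[o] += cfx * w;
            GY[o] += cfy * w;
          }
        }
      }
    }
  }
  if (n_in == 0)
    return List::create(_["value"] = NA_REAL, _["gx"] = gx, _["gy"] = gy, _["n_in"] = 0);
  E /= (double)n_in;
  if (want_grad) {
    double inv = 1.0 / (double)n_in;
    for (int i = 0; i < nl * nk; ++i) { GX[i] *= inv; GY[i] *= inv; }
  }
  return List::create(_["value"] = E, _["gx"] = gx, _["gy"] = gy,
                      _["n_in"] = (double)n_in);
}

// Divergence and curl regularization energies of the displacement
// u = g(x,y) - (x,y):  E_div = mean (du/dx + dv/dy)^2,
// E_rot = mean (dv/dx - du/dy)^2, with analytic coefficient gradients.
// [[Rcpp::export]]
List cpp_ereg_grad(NumericMatrix cx, NumericMatrix cy,
                   double sx, double sy, int W, int H, bool want_grad) {
  int nk = cx.ncol(), nl = cx.nrow();
  const double *CX = cx.begin(), *CY = cy.begin();
  NumericMatrix gdx(nl, nk), gdy(nl, nk), grx(nl, nk), gry(nl, nk);
  double *GDX = gdx.begin(), *GDY = gdy.begin(), *GRX = grx.begin(), *GRY = gry.begin();
  BasisTables T(W, H, sx, sy, nk, nl);
  double Ediv = 0.0, Erot = 0.0;
  double N = (double)W * H, invN = 1.0 / N;
  for (int x = 0; x < W; ++x) {
    const int *ixp = &T.ix[4*x];
    const double *wxp = &T.wx[4*x], *dwxp = &T.dwx[4*x];
    for (int y = 0; y < H; ++y) {
      const int *iyp = &T.iy[4*y];
      const double *wyp = &T.wy[4*y], *dwyp = &T.dwy[4*y];
      double gxx = 0.0, gxy = 0.0, gyx = 0.0, gyy = 0.0;
      for (int b = 0; b < 4; ++b) {
        int r = iyp[b];
        double wyb = wyp[b], dwyb = dwyp[b];
        if (wyb == 0.0 && dwyb == 0.0) continue;
        for (int a = 0; a < 4; ++a) {
          size_t o = (size_t)ixp[a] * nl + r;
          double cxv = CX[o], cyv = CY[o];
          double wa = wxp[a], da = dwxp[a];
          gxx += cxv * da * wyb;   // d gx / dx
          gxy += cxv * wa * dwyb;  // d gx / dy
          gyx += cyv * da * wyb;   // d gy / dx
          gyy += cyv * wa * dwyb;  // d gy / dy
        }
      }
      double div = (gxx - 1.0) + (gyy - 1.0);
      double rot = gyx - gxy;
      Ediv += div * div;
      Erot += rot * rot;
      if (want_grad) {
        double cdiv = 2.0 * div * invN, crot = 2.0 * rot * invN;
        for (int b = 0; b < 4; ++b) {
          int r = iyp[b];
          double wyb = wyp[b], dwyb = dwyp[b];
          if (wyb == 0.0 && dwyb == 0.0) continue;
          for (int a = 0; a < 4; ++a) {
            size_t o = (size_t)ixp[a] * nl + r;
            double dw = dwxp[a] * wyb, wd = wxp[a] * dwyb;
            GDX[o] += cdiv * dw;
            GDY[o] += cdiv * wd;
            GRX[o] += -crot * wd;
            GRY[o] += crot * dw;
          }
        }
      }
    }
  }
  return List::create(_["ediv"] = Ediv / N, _["erot"] = Erot / N,
                      _["gdx"] = gdx, _["gdy"] = gdy,
                      _["grx"] = grx, _["gry"] = gry);
}

// Evaluate a field and its Jacobian at one point (raw buffers).
static inline void field_at(const double *CX, const double *CY, int nk, int nl,
                            double sx, double sy, double x, double y,
                            double &fx, double &fy,
                            double &j11, double &j12, double &j21, double &j22) {
  int ix[4], iy[4];
  double wx[4], wy[4], dwx[4], dwy[4];
  basis1d(x, sx, nk, ix, wx, dwx);
  basis1d(y, sy, nl, iy, wy, dwy);
  fx = fy = j11 = j12 = j21 = j22 = 0.0;
  for (int b = 0; b < 4; ++b) {
    if (wy[b] == 0.0 && dwy[b] == 0.0) continue;
    for (int a = 0; a < 4; ++a) {
      size_t o = (size_t)ix[a] * nl + iy[b];
      double cxv = CX[o], cyv = CY[o];
      fx += cxv * wx[a] * wy[b];
      fy += cyv * wx[a] * wy[b];
      j11 += cxv * dwx[a] * wy[b];
      j12 += cxv * wx[a] * dwy[b];
      j21 += cyv * dwx[a] * wy[b];
      j22 += cyv * wx[a] * dwy[b];
    }
  }
}

// One directed consistency pass: mean over sampled x of
// ||outer(inner(x)) - x||^2, gradients accumulated unnormalized.
static void econs_pass(const double *icx, const double *icy,
                       const double *ocx, const double *ocy, int nk, int nl,
                       double sx, double sy, int W, int H, int stride,
                       bool want_grad,
                       double *gix, double *giy, double *gox, double *goy,
                       double &energy, long &count) {
  int ix[4], iy[4];
  double wx[4], wy[4], dwx[4], dwy[4];
  energy = 0.0; count = 0;
  for (int x = 0; x < W; x += stride) {
    for (int y = 0; y < H; y += stride) {
      double mx, my, a11, a12, a21, a22;
      field_at(icx, icy, nk, nl, sx, sy, (double)x, (double)y, mx, my, a11, a12, a21, a22);
      if (mx < 0.0 || my < 0.0 || mx > W - 1.0 || my > H - 1.0) continue;
      double ox_, oy_, j11, j12, j21, j22;
      field_at(ocx, ocy, nk, nl, sx, sy, mx, my, ox_, oy_, j11, j12, j21, j22);
      double rx = ox_ - x, ry = oy_ - y;
      energy += rx * rx + ry * ry;
      ++count;
      if (want_grad) {
        // outer field coefficients: basis at the intermediate point
        basis1d(mx, sx, nk, ix, wx, dwx);
        basis1d(my, sy, nl, iy, wy, dwy);
        for (int b = 0; b < 4; ++b) {
          if (wy[b] == 0.0) continue;
          for (int a = 0; a < 4; ++a) {
            double w = wx[a] * wy[b]; if (w == 0.0) continue;
            size_t o = (size_t)ix[a] * nl + iy[b];
            gox[o] += 2.0 * rx * w;
            goy[o] += 2.0 * ry * w;
          }
        }
        // inner field coefficients: chain rule through the outer Jacobian
        basis1d((double)x, sx, nk, ix, wx, dwx);
        basis1d((double)y, sy, nl, iy, wy, dwy);
        double cx_fac = 2.0 * (rx * j11 + ry * j21);
        double cy_fac = 2.0 * (rx * j12 + ry * j22);
        for (int b = 0; b < 4; ++b) {
          if (wy[b] == 0.0) continue;
          for (int a = 0; a < 4; ++a) {
            double w = wx[a] * wy[b]; if (w == 0.0) continue;
            size_t o = (size_t)ix[a] * nl + iy[b];
            gix[o] += cx_fac * w;
            giy[o] += cy_fac * w;
          }
        }
      }
    }
  }
}

// Bidirectional consistency energy:
// 0.5 * [ mean_x ||f_ts(f_st(x)) - x||^2 + mean_x ||f_st(f_ts(x)) - x||^2 ]
// over a stride-subsampled pixel grid; samples whose intermediate point
// leaves the domain are excluded from the corresponding mean.
// [[Rcpp::export]]
List cpp_econs_grad(NumericMatrix cxst, NumericMatrix cyst,
                    NumericMatrix cxts, NumericMatrix cyts,
                    double sx, double sy, int W, int H,
                    int stride, bool want_grad) {
  int nk = cxst.ncol(), nl = cxst.nrow();
  int nc = nk * nl;
  NumericMatrix g_stx(nl, nk), g_sty(nl, nk), g_tsx(nl, nk), g_tsy(nl, nk);
  double val = 0.0;
  std::vector<double> tix(nc), tiy(nc), tox(nc), toy(nc);
  for (int pass = 0; pass < 2; ++pass) {
    std::fill(tix.begin(), tix.end(), 0.0);
    std::fill(tiy.begin(), tiy.end(), 0.0);
    std::fill(tox.begin(), tox.end(), 0.0);
    std::fill(toy.begin(), toy.end(), 0.0);
    double e; long cnt;
    if (pass == 0)
      econs_pass(cxst.begin(), cyst.begin(), cxts.begin(), cyts.begin(),
                 nk, nl, sx, sy, W, H, stride, want_grad,
                 &tix[0], &tiy[0], &tox[0], &toy[0], e, cnt);
    else
      econs_pass(cxts.begin(), cyts.begin(), cxst.begin(), cyst.begin(),
                 nk, nl, sx, sy, W, H, stride, want_grad,
                 &tix[0], &tiy[0], &tox[0], &toy[0], e, cnt);
    if (cnt == 0) continue;
    double f = 0.5 / (double)cnt;
    val += e * f;
    if (want_grad) {
      double *ix_ = pass == 0 ? g_stx.begin() : g_tsx.begin();
      double *iy_ = pass == 0 ? g_sty.begin() : g_tsy.begin();
      double *ox_ = pass == 0 ? g_tsx.begin() : g_stx.begin();
      double *oy_ = pass == 0 ? g_tsy.begin() : g_sty.begin();
      for (int i = 0; i < nc; ++i) {
        ix_[i] += tix[i] * f;
        iy_[i] += tiy[i] * f;
        ox_[i] += tox[i] * f;
        oy_[i] += toy[i] * f;
      }
    }
  }
  return List::create(_["value"] = val,
                      _["g_stx"] = g_stx, _["g_sty"] = g_sty,
                      _["g_tsx"] = g_tsx, _["g_tsy"] = g_tsy);
}

// Block-mean downsampling by integer factor (trailing remainder cropped).
// [[Rcpp::export]]
NumericMatrix cpp_downsample(NumericMatrix img, int f) {
  int H = img.nrow() / f, W = img.ncol() / f;
  int sH = img.nrow();
  const double *I = img.begin();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int a = 0; a < f; ++a)
        for (int b = 0; b < f; ++b)
          s += I[(size_t)(x * f + a) * sH + (y * f + b)];
      out(y, x) = s / (f * f);
    }
  return out;
}
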