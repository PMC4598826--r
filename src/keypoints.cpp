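#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Small float-image buffer used by the scale-space machinery.
struct FImg {
  int w, h;
  std::vector<double> d;
  FImg(int w_, int h_) : w(w_), h(h_), d((size_t)w_ * h_, 0.0) {}
  inline double at(int x, int y) const { return d[(size_t)y * w + x]; }
  inline double &at(int x, int y) { return d[(size_t)y * w + x]; }
};

// Reflective border access.
static inline int refl(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

static FImg gauss_blur(const FImg &src, double sigma) {
  if (sigma <= 0.0) return src;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &v : k) v /= s;
  FImg tmp(src.w, src.h), out(src.w, src.h);
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += k[i + r] * src.at(refl(x + i, src.w), y);
      tmp.at(x, y) = a;
    }
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += k[i + r] * tmp.at(x, refl(y + i, src.h));
      out.at(x, y) = a;
    }
  return out;
}

static FImg half(const FImg &src) {
  FImg out(src.w / 2, src.h / 2);
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x)
      out.at(x, y) = src.at(2 * x, 2 * y);
  return out;
}

// Separable Gaussian blur, exported for texture synthesis and tests.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  FImg f(img.ncol(), img.nrow());
  for (int y = 0; y < f.h; ++y) for (int x = 0; x < f.w; ++x) f.at(x, y) = img(y, x);
  FImg b = gauss_blur(f, sigma);
  NumericMatrix out(img.nrow(), img.ncol());
  for (int y = 0; y < f.h; ++y) for (int x = 0; x < f.w; ++x) out(y, x) = b.at(x, y);
  return out;
}

struct Kp { double x, y, scale, ori; int octave; double desc[128]; };

static void descriptor(const FImg &g, double x, double y, double sigma,
                       double ori, double *out) {
  const int d = 4, nb = 8;
  double cost = std::cos(-ori), sint = std::sin(-ori);
  double hist_w = 3.0 * sigma;
  int radius = (int)std::round(hist_w * std::sqrt(2.0) * (d + 1) * 0.5);
  double hist[d + 2][d + 2][nb + 2];
  std::memset(hist, 0, sizeof(hist));
  int xi = (int)std::round(x), yi = (int)std::round(y);
  for (int dy = -radius; dy <= radius; ++dy) {
    for (int dx = -radius; dx <= radius; ++dx) {
      int px = xi + dx, py = yi + dy;
      if (px < 1 || py < 1 || px >= g.w - 1 || py >= g.h - 1) continue;
      double rx = (cost * dx - sint * dy) / hist_w;
      double ry = (sint * dx + cost * dy) / hist_w;
      double rbin = ry + d / 2.0 - 0.5, cbin = rx + d / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      double gx = g.at(px + 1, py) - g.at(px - 1, py);
      double gy = g.at(px, py + 1) - g.at(px, py - 1);
      double mag = std::sqrt(gx * gx + gy * gy);
      double theta = std::atan2(gy, gx) - ori;
      while (theta < 0) theta += 2 * M_PI;
      while (theta >= 2 * M_PI) theta -= 2 * M_PI;
      double obin = theta * nb / (2 * M_PI);
      double wgt = std::exp(-(rx * rx + ry * ry) / (0.5 * d * d)) * mag;
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin), o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int ir = 0; ir <= 1; ++ir) {
        int rr = r0 + ir + 1; if (rr < 0 || rr > d + 1) continue;
        double wr = wgt * (ir ? fr : 1 - fr);
        for (int ic = 0; ic <= 1; ++ic) {
          int cc = c0 + ic + 1; if (cc < 0 || cc > d + 1) continue;
          double wc = wr * (ic ? fc : 1 - fc);
          for (int io = 0; io <= 1; ++io) {
            int oo = (o0 + io) % nb;
            hist[rr][cc][oo] += wc * (io ? fo : 1 - fo);
          }
        }
      }
    }
  }
  int idx = 0;
  for (int rr = 1; rr <= d; ++rr)
    for (int cc = 1; cc <= d; ++cc)
      for (int oo = 0; oo < nb; ++oo)
        out[idx++] = hist[rr][cc][oo];
  double nrm = 0.0;
  for (int i = 0; i < 128; ++i) nrm += out[i] * out[i];
  nrm = std::sqrt(nrm);
  if (nrm < 1e-12) return;
  for (int i = 0; i < 128; ++i) { out[i] /= nrm; if (out[i] > 0.2) out[i] = 0.2; }
  nrm = 0.0;
  for (int i = 0; i < 128; ++i) nrm += out[i] * out[i];
  nrm = std::sqrt(nrm);
  for (int i = 0; i < 128; ++i) out[i] /= nrm;
}

// Difference-of-Gaussian keypoint detector with SIFT-style gradient
// descriptors.  img: H x W in [0,255].  Deterministic.
// [[Rcpp::export]]
List cpp_detect_dog(NumericMatrix img, int nspo, double sigma0,
                    double contrast_thr, double edge_r, int max_keypoints) {
  int W = img.ncol(), H = img.nrow();
  FImg base(W, H);
  for (int y = 0; y < H; ++y) for (int x = 0; x < W; ++x) base.at(x, y) = img(y, x) / 255.0;
  // assumed camera blur 0.5 px -> bring to sigma0
  double diff = sigma0 * sigma0 - 0.25;
  if (diff > 0) base = gauss_blur(base, std::sqrt(diff));
  int noct = 1;
  { int m = std::min(W, H); while ((m >> (noct)) >= 32 && noct < 6) ++noct; }
  std::vector<Kp> kps;
  double edge_lim = (edge_r + 1.0) * (edge_r + 1.0) / edge_r;
  FImg oct_base = base;
  for (int o = 0; o < noct; ++o) {
    std::vector<FImg> gs; gs.reserve(nspo + 3);
    gs.push_back(oct_base);
    for (int s = 1; s < nspo + 3; ++s) {
      double sp = sigma0 * std::pow(2.0, (double)(s - 1) / nspo);
      double sc = sigma0 * std::pow(2.0, (double)s / nspo);
      gs.push_back(gauss_blur(gs[s - 1], std::sqrt(sc * sc - sp * sp)));
    }
    std::vector<FImg> dog; dog.reserve(nspo + 2);
    for (int s = 0; s < nspo + 2; ++s) {
      FImg d(gs[0].w, gs[0].h);
      for (size_t i = 0; i < d.d.size(); ++i) d.d[i] = gs[s + 1].d[i] - gs[s].d[i];
      dog.push_back(d);
    }
    int w = gs[0].w, h = gs[0].h;
    for (int s = 1; s <= nspo; ++s) {
      const FImg &D = dog[s], &Dm = dog[s - 1], &Dp = dog[s + 1];
      for (int y = 5; y < h - 5; ++y) {
        for (int x = 5; x < w - 5; ++x) {
          double v = D.at(x, y);
          if (std::fabs(v) < contrast_thr) continue;
          bool mx = true, mn = true;
          for (int b = -1; b <= 1 && (mx || mn); ++b)
            for (int a = -1; a <= 1; ++a) {
              double n1 = Dm.at(x + a, y + b), n2 = D.at(x + a, y + b), n3 = Dp.at(x + a, y + b);
              if (n1 > v || n3 > v || (n2 > v && !(a == 0 && b == 0))) mx = false;
              if (n1 < v || n3 < v || (n2 < v && !(a == 0 && b == 0))) mn = false;
            }
          if (!mx && !mn) continue;
          double dxx = D.at(x + 1, y) + D.at(x - 1, y) - 2 * v;
          double dyy = D.at(x, y + 1) + D.at(x, y - 1) - 2 * v;
          double dxy = (D.at(x + 1, y + 1) - D.at(x - 1, y + 1) -
                        D.at(x + 1, y - 1) + D.at(x - 1, y - 1)) / 4.0;
          double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
          if (det <= 0 || tr * tr / det >= edge_lim) continue;
          double sig_rel = sigma0 * std::pow(2.0, (double)s / nspo);
          // dominant gradient orientation (36-bin weighted histogram)
          const FImg &G = gs[s];
          double hist[36] = {0};
          double sigw = 1.5 * sig_rel;
          int rad = (int)std::round(3.0 * sigw);
          for (int b = -rad; b <= rad; ++b)
            for (int a = -rad; a <= rad; ++a) {
              int px = x + a, py = y + b;
              if (px < 1 || py < 1 || px >= w - 1 || py >= h - 1) continue;
              double gx = G.at(px + 1, py) - G.at(px - 1, py);
              double gy = G.at(px, py + 1) - G.at(px, py - 1);
              double mag = std::sqrt(gx * gx + gy * gy);
              double th = std::atan2(gy, gx);
              if (th < 0) th += 2 * M_PI;
              int bin = (int)(th * 36 / (2 * M_PI)) % 36;
              hist[bin] += mag * std::exp(-0.5 * (a * a + b * b) / (sigw * sigw));
            }
          for (int it = 0; it < 2; ++it) { // circular smoothing
            double prev = hist[35], h0 = hist[0];
            for (int i = 0; i < 36; ++i) {
              double cur = hist[i];
              double nxt = (i == 35) ? h0 : hist[i + 1];
              hist[i] = (prev + cur + nxt) / 3.0;
              prev = cur;
            }
          }
          int pk = 0;
          for (int i = 1; i < 36; ++i) if (hist[i] > hist[pk]) pk = i;
          double l = hist[(pk + 35) % 36], c = hist[pk], r = hist[(pk + 1) % 36];
          double off = (l - r) / (2 * (l - 2 * c + r + 1e-12));
          double ori = (pk + 0.5 + off) * 2 * M_PI / 36;
          Kp kp;
          kp.x = x * std::pow(2.0, o); kp.y = y * std::pow(2.0, o);
          kp.scale = sig_rel * std::pow(2.0, o);
          kp.ori = ori; kp.octave = o;
          descriptor(G, x, y, sig_rel, ori, kp.desc);
          double nn = 0.0;
          for (int i = 0; i < 128; ++i) nn += kp.desc[i] * kp.desc[i];
          if (nn < 0.5) continue; // flat patch, useless descriptor
          kps.push_back(kp);
          if ((int)kps.size() >= max_keypoints) goto done;
        }
      }
    }
    if (o + 1 < noct) oct_base = half(gs[nspo]);
  }
done:
  int n = kps.size();
  NumericMatrix pts(n, 4), desc(n, 128);
  for (int i = 0; i < n; ++i) {
    pts(i, 0) = kps[i].x; pts(i, 1) = kps[i].y;
    pts(i, 2) = kps[i].scale; pts(i, 3) = kps[i].ori;
    for (int j = 0; j < 128; ++j) desc(i, j) = kps[i].desc[j];
  }
  colnames(pts) = CharacterVector::create("x", "y", "scale", "orientation");
  return List::create(_["points"] = pts, _["descriptors"] = desc);
}

// True for pixels <= tol that are 4-connected to the image border
// (the "real" background; enclosed dark holes stay false).
// [[Rcpp::export]]
LogicalMatrix cpp_background_mask(NumericMatrix img, double tol) {
  int H = img.nrow(), W = img.ncol();
  LogicalMatrix bg(H, W);
  std::vector<int> stack;
  stack.reserve(2 * (W + H));
  auto push = [&](int x, int y) {
    if (x < 0 || y < 0 || x >= W || y >= H) return;
    if (bg(y, x) || img(y, x) > tol) return;
    bg(y, x) = true;
    stack.push_back(y * W + x);
  };
  for (int x = 0; x < W; ++x) { push(x, 0); push(x, H - 1); }
  for (int y = 0; y < H; ++y) { push(0, y); push(W - 1, y); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int x = p % W, y = p / W;
    push(x + 1, y); push(x - 1, y); push(x, y + 1); push(x, y - 1);
  }
  return bg;
}
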