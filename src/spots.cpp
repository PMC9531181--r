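#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable scale-normalized Laplacian-of-Gaussian blob response and local
// maxima, evaluated per frame over a whole movie stack. Stacks are stored
// column-major as H x W x F (row = y, column = x), 0-based frame indices.
// ---------------------------------------------------------------------------

static void gauss_kernels(double sigma, std::vector<double> &g,
                          std::vector<double> &gxx, int &r) {
  r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  g.assign(2 * r + 1, 0.0);
  gxx.assign(2 * r + 1, 0.0);
  double s2 = sigma * sigma, sum = 0.0;
  for (int k = -r; k <= r; ++k) {
    double e = std::exp(-0.5 * k * k / s2);
    g[k + r] = e;
    sum += e;
  }
  for (int k = -r; k <= r; ++k) {
    g[k + r] /= sum;
    gxx[k + r] = g[k + r] * (k * k - s2) / (s2 * s2);
  }
  // remove DC leakage of the discrete second-derivative kernel
  double m = 0.0;
  for (double v : gxx) m += v;
  m /= (2 * r + 1);
  for (double &v : gxx) v -= m;
}

// 1D convolution along rows (x) or columns (y) with replicated edges
static void conv_cols(const std::vector<double> &in, std::vector<double> &out,
                      int H, int W, const std::vector<double> &k, int r) {
  for (int x = 0; x < W; ++x) {
    const double *col = &in[(size_t)H * x];
    double *o = &out[(size_t)H * x];
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int yy = y + t;
        if (yy < 0) yy = 0;
        if (yy >= H) yy = H - 1;
        acc += col[yy] * k[t + r];
      }
      o[y] = acc;
    }
  }
}

static void conv_rows(const std::vector<double> &in, std::vector<double> &out,
                      int H, int W, const std::vector<double> &k, int r) {
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int xx = x + t;
        if (xx < 0) xx = 0;
        if (xx >= W) xx = W - 1;
        acc += in[(size_t)H * xx + y] * k[t + r];
      }
      out[(size_t)H * x + y] = acc;
    }
  }
}

struct Cand {
  int frame;
  double x, y, sigma, resp;
};

// robust sigma (1.4826 * MAD) of a response image, on a pixel subsample
static double robust_sigma(const std::vector<double> &r, int step) {
  std::vector<double> v;
  v.reserve(r.size() / step + 1);
  for (size_t i = 0; i < r.size(); i += step) v.push_back(r[i]);
  size_t m = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  double med = v[m];
  for (double &x : v) x = std::fabs(x - med);
  std::nth_element(v.begin(), v.begin() + m, v.end());
  return 1.4826 * v[m];
}

// [[Rcpp::export(name = ".log_detect_cpp")]]
DataFrame log_detect_cpp(NumericVector stack, int H, int W, int F,
                         NumericVector sigmas, double threshold_rel,
                         double min_sep_factor, double noise_floor_k) {
  int ns = sigmas.size();
  std::vector<std::vector<double> > gk(ns), gxxk(ns);
  std::vector<int> rk(ns);
  for (int s = 0; s < ns; ++s) gauss_kernels(sigmas[s], gk[s], gxxk[s], rk[s]);

  size_t npx = (size_t)H * W;
  std::vector<double> frame(npx), tmp(npx), respA(npx), respB(npx);
  std::vector<std::vector<double> > resp(ns, std::vector<double>(npx));
  std::vector<Cand> all;

  for (int f = 0; f < F; ++f) {
    const double *fp = &stack[(size_t)f * npx];
    double fmin = fp[0], fmax = fp[0];
    for (size_t i = 0; i < npx; ++i) {
      frame[i] = fp[i];
      if (fp[i] < fmin) fmin = fp[i];
      if (fp[i] > fmax) fmax = fp[i];
    }
    double thr_rng = threshold_rel * (fmax - fmin);
    if (thr_rng <= 0) continue;

    std::vector<double> thr_s(ns);
    for (int s = 0; s < ns; ++s) {
      double s2 = sigmas[s] * sigmas[s];
      // -sigma^2 * (Gxx*G + G*Gyy) convolved with frame
      conv_rows(frame, tmp, H, W, gxxk[s], rk[s]);
      conv_cols(tmp, respA, H, W, gk[s], rk[s]);
      conv_rows(frame, tmp, H, W, gk[s], rk[s]);
      conv_cols(tmp, respB, H, W, gxxk[s], rk[s]);
      for (size_t i = 0; i < npx; ++i)
        resp[s][i] = -s2 * (respA[i] + respB[i]);
      // guard against pure-noise frames: the range-relative threshold is
      // meaningless when no real structure sets the range
      thr_s[s] = thr_rng;
      if (noise_floor_k > 0) {
        double flr = noise_floor_k * robust_sigma(resp[s], 4);
        if (flr > thr_s[s]) thr_s[s] = flr;
      }
    }

    std::vector<Cand> fc;
    for (int s = 0; s < ns; ++s) {
      const std::vector<double> &R = resp[s];
      double thr = thr_s[s];
      for (int x = 1; x < W - 1; ++x) {
        for (int y = 1; y < H - 1; ++y) {
          double v = R[(size_t)H * x + y];
          if (v < thr) continue;
          bool mx = v > R[(size_t)H * (x - 1) + y] &&
                    v >= R[(size_t)H * (x + 1) + y] &&
                    v > R[(size_t)H * x + y - 1] &&
                    v >= R[(size_t)H * x + y + 1] &&
                    v > R[(size_t)H * (x - 1) + y - 1] &&
                    v > R[(size_t)H * (x - 1) + y + 1] &&
                    v >= R[(size_t)H * (x + 1) + y - 1] &&
                    v >= R[(size_t)H * (x + 1) + y + 1];
          if (mx) {
            Cand c;
            c.frame = f;
            c.x = x;
            c.y = y;
            c.sigma = sigmas[s];
            c.resp = v;
            fc.push_back(c);
          }
        }
      }
    }
    // merge overlapping responses across scales, keep the stronger
    std::sort(fc.begin(), fc.end(),
              [](const Cand &a, const Cand &b) { return a.resp > b.resp; });
    std::vector<Cand> kept;
    for (const Cand &c : fc) {
      bool ok = true;
      for (const Cand &k : kept) {
        double d2 = (c.x - k.x) * (c.x - k.x) + (c.y - k.y) * (c.y - k.y);
        double rad = min_sep_factor * std::max(c.sigma, k.sigma);
        if (d2 < rad * rad) {
          ok = false;
          break;
        }
      }
      if (ok) kept.push_back(c);
    }
    for (const Cand &c : kept) all.push_back(c);
  }

  int n = all.size();
  IntegerVector ofr(n);
  NumericVector ox(n), oy(n), osig(n), oresp(n);
  for (int i = 0; i < n; ++i) {
    ofr[i] = all[i].frame;
    ox[i] = all[i].x;
    oy[i] = all[i].y;
    osig[i] = all[i].sigma;
    oresp[i] = all[i].resp;
  }
  return DataFrame::create(_["frame"] = ofr, _["x"] = ox, _["y"] = oy,
                           _["scale"] = osig, _["response"] = oresp);
}

// ---------------------------------------------------------------------------
// Batched Levenberg-Marquardt fits of the 6-parameter 2D Gaussian
//   I(x, y) = A exp(-(x-x0)^2/(2 sx^2) - (y-y0)^2/(2 sy^2)) + b
// over square windows centred on candidate pixels.
// ---------------------------------------------------------------------------

static bool solve6(double M[6][6], double v[6], double out[6]) {
  int idx[6] = {0, 1, 2, 3, 4, 5};
  double a[6][7];
  for (int i = 0; i < 6; ++i) {
    for (int j = 0; j < 6; ++j) a[i][j] = M[i][j];
    a[i][6] = v[i];
  }
  for (int c = 0; c < 6; ++c) {
    int p = c;
    for (int i = c + 1; i < 6; ++i)
      if (std::fabs(a[i][c]) > std::fabs(a[p][c])) p = i;
    if (std::fabs(a[p][c]) < 1e-300) return false;
    if (p != c)
      for (int j = c; j < 7; ++j) std::swap(a[c][j], a[p][j]);
    for (int i = c + 1; i < 6; ++i) {
      double m = a[i][c] / a[c][c];
      for (int j = c; j < 7; ++j) a[i][j] -= m * a[c][j];
    }
  }
  for (int i = 5; i >= 0; --i) {
    double acc = a[i][6];
    for (int j = i + 1; j < 6; ++j) acc -= a[i][j] * out[j];
    out[i] = acc / a[i][i];
  }
  (void)idx;
  return true;
}

// [[Rcpp::export(name = ".gaussfit_cpp")]]
NumericMatrix gaussfit_cpp(NumericVector stack, int H, int W, int F,
                           IntegerVector frame, NumericVector cx,
                           NumericVector cy, NumericVector sigma0, int w,
                           int max_iter, double tol) {
  int n = frame.size();
  NumericMatrix out(n, 9);
  colnames(out) = CharacterVector::create("amplitude", "x", "y", "sigma_x",
                                          "sigma_y", "offset", "converged",
                                          "rss", "n_iter");
  size_t npx = (size_t)H * W;
  int side = 2 * w + 1, P = side * side;
  std::vector<double> I(P), r(P), Jc[6];
  for (int j = 0; j < 6; ++j) Jc[j].assign(P, 0.0);

  for (int i = 0; i < n; ++i) {
    int f = frame[i];
    int xi = (int)std::lround(cx[i]), yi = (int)std::lround(cy[i]);
    if (f < 0 || f >= F || xi - w < 0 || xi + w >= W || yi - w < 0 ||
        yi + w >= H) {
      out(i, 6) = -1; // window clipped by image edge
      continue;
    }
    const double *fp = &stack[(size_t)f * npx];
    double imin = R_PosInf, imax = R_NegInf;
    for (int dx = -w; dx <= w; ++dx)
      for (int dy = -w; dy <= w; ++dy) {
        double v = fp[(size_t)H * (xi + dx) + (yi + dy)];
        I[(dx + w) * side + (dy + w)] = v;
        if (v < imin) imin = v;
        if (v > imax) imax = v;
      }
    // theta = A, x0, y0, sx, sy, b
    double th[6] = {imax - imin, cx[i], cy[i], sigma0[i], sigma0[i], imin};
    if (th[0] <= 0) { // flat window, nothing to fit
      out(i, 0) = th[0]; out(i, 1) = th[1]; out(i, 2) = th[2];
      out(i, 3) = th[3]; out(i, 4) = th[4]; out(i, 5) = th[5];
      out(i, 6) = 0;
      continue;
    }
    double lambda = 1e-3, rss = 0.0;
    bool conv = false;
    int it = 0;
    auto resid = [&](const double t[6]) {
      double s = 0.0;
      for (int dx = -w; dx <= w; ++dx)
        for (int dy = -w; dy <= w; ++dy) {
          double ex = (xi + dx - t[1]) / t[3], ey = (yi + dy - t[2]) / t[4];
          double m = t[0] * std::exp(-0.5 * (ex * ex + ey * ey)) + t[5];
          double rr = I[(dx + w) * side + (dy + w)] - m;
          s += rr * rr;
        }
      return s;
    };
    rss = resid(th);
    for (it = 0; it < max_iter; ++it) {
      // residuals and Jacobian at th
      int p = 0;
      for (int dx = -w; dx <= w; ++dx)
        for (int dy = -w; dy <= w; ++dy, ++p) {
          double ddx = xi + dx - th[1], ddy = yi + dy - th[2];
          double sx2 = th[3] * th[3], sy2 = th[4] * th[4];
          double E = std::exp(-0.5 * (ddx * ddx / sx2 + ddy * ddy / sy2));
          double m = th[0] * E + th[5];
          r[p] = I[(dx + w) * side + (dy + w)] - m;
          Jc[0][p] = E;
          Jc[1][p] = th[0] * E * ddx / sx2;
          Jc[2][p] = th[0] * E * ddy / sy2;
          Jc[3][p] = th[0] * E * ddx * ddx / (sx2 * th[3]);
          Jc[4][p] = th[0] * E * ddy * ddy / (sy2 * th[4]);
          Jc[5][p] = 1.0;
        }
      double JtJ[6][6], Jtr[6];
      for (int a = 0; a < 6; ++a) {
        Jtr[a] = 0.0;
        for (int b = a; b < 6; ++b) {
          double acc = 0.0;
          for (int q = 0; q < P; ++q) acc += Jc[a][q] * Jc[b][q];
          JtJ[a][b] = JtJ[b][a] = acc;
        }
        for (int q = 0; q < P; ++q) Jtr[a] += Jc[a][q] * r[q];
      }
      bool stepped = false;
      for (int attempt = 0; attempt < 8; ++attempt) {
        double M[6][6], d[6], tn[6];
        for (int a = 0; a < 6; ++a)
          for (int b = 0; b < 6; ++b)
            M[a][b] = JtJ[a][b] + (a == b ? lambda * JtJ[a][a] : 0.0);
        if (!solve6(M, Jtr, d)) {
          lambda *= 10;
          continue;
        }
        for (int a = 0; a < 6; ++a) tn[a] = th[a] + d[a];
        if (tn[3] <= 0.05) tn[3] = 0.05;
        if (tn[4] <= 0.05) tn[4] = 0.05;
        double rss_new = resid(tn);
        if (rss_new <= rss) {
          double rel = 0.0;
          for (int a = 0; a < 6; ++a) {
            double sc = std::max(std::fabs(th[a]), 1e-6);
            rel = std::max(rel, std::fabs(d[a]) / sc);
          }
          for (int a = 0; a < 6; ++a) th[a] = tn[a];
          double drop = rss - rss_new;
          rss = rss_new;
          lambda = std::max(lambda / 3.0, 1e-12);
          stepped = true;
          if (rel < tol || drop <= 1e-12 * (rss + 1e-12)) conv = true;
          break;
        }
        lambda *= 4.0;
      }
      if (!stepped) { // cannot improve: treat as converged to local optimum
        conv = true;
      }
      if (conv) break;
    }
    th[3] = std::fabs(th[3]);
    th[4] = std::fabs(th[4]);
    out(i, 0) = th[0]; out(i, 1) = th[1]; out(i, 2) = th[2];
    out(i, 3) = th[3]; out(i, 4) = th[4]; out(i, 5) = th[5];
    out(i, 6) = conv ? 1 : 0;
    out(i, 7) = rss;
    out(i, 8) = it + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Add symmetric/asymmetric 2D Gaussian point-spread functions into a stack
// (in place; the caller owns the only reference).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".render_spots_cpp")]]
void render_spots_cpp(NumericVector stack, int H, int W, int F,
                      IntegerVector frame, NumericVector x, NumericVector y,
                      NumericVector amp, NumericVector sx, NumericVector sy,
                      double half_sigmas) {
  size_t npx = (size_t)H * W;
  for (int i = 0; i < frame.size(); ++i) {
    int f = frame[i];
    if (f < 0 || f >= F) continue;
    double *fp = &stack[(size_t)f * npx];
    int r = (int)std::ceil(half_sigmas * std::max(sx[i], sy[i]));
    int x0 = std::max(0, (int)std::floor(x[i]) - r);
    int x1 = std::min(W - 1, (int)std::ceil(x[i]) + r);
    int y0 = std::max(0, (int)std::floor(y[i]) - r);
    int y1 = std::min(H - 1, (int)std::ceil(y[i]) + r);
    double isx2 = 0.5 / (sx[i] * sx[i]), isy2 = 0.5 / (sy[i] * sy[i]);
    for (int xx = x0; xx <= x1; ++xx) {
      double dx2 = (xx - x[i]) * (xx - x[i]) * isx2;
      for (int yy = y0; yy <= y1; ++yy) {
        double dy2 = (yy - y[i]) * (yy - y[i]) * isy2;
        fp[(size_t)H * xx + yy] += amp[i] * std::exp(-(dx2 + dy2));
      }
    }
  }
}
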