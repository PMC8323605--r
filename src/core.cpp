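#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adaptive per-pixel Gaussian mixture background subtraction.
//
// frames:    list of H x W numeric matrices, gray levels 0..255
// init_mean: H x W matrix used to seed the first component of every pixel
//            (weight 1); typically a temporal median over the burn-in window
// alpha:     learning-rate constant in (0,1); weights relax as
//            w <- (1-alpha) w + alpha o, so a newly created component needs
//            about log(1-cf)/log(1-alpha) matched frames before its weight
//            exceeds cf
// cf:        background weight threshold: a pixel is background only when its
//            matched component carries weight > cf
// max_k:     maximum number of components kept per pixel
// var_init:  variance given to newly created components (gray^2)
// var_min:   variance floor (keeps the match window from collapsing)
// match_k:   a value matches a component when |x - mu| < match_k * sigma
//
// Returns a list of H x W logical matrices (TRUE = foreground).
// [[Rcpp::export]]
List gmm_foreground_cpp(List frames, NumericMatrix init_mean,
                        double alpha, double cf, int max_k,
                        double var_init, double var_min, double match_k) {
  const int T = frames.size();
  NumericMatrix f0 = frames[0];
  const int H = f0.nrow(), W = f0.ncol();
  const R_xlen_t npx = (R_xlen_t)H * W;
  std::vector<double> w(npx * max_k, 0.0);
  std::vector<double> mu(npx * max_k, 0.0);
  std::vector<double> var(npx * max_k, 0.0);
  std::vector<int> nk(npx, 1);
  for (R_xlen_t p = 0; p < npx; ++p) {
    w[p * max_k] = 1.0;
    mu[p * max_k] = init_mean[p];
    var[p * max_k] = var_init;
  }
  const double k2 = match_k * match_k;
  List out(T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix fr = frames[t];
    if (fr.nrow() != H || fr.ncol() != W)
      stop("frame %d has mismatched dimensions", t + 1);
    LogicalMatrix mask(H, W);
    for (R_xlen_t p = 0; p < npx; ++p) {
      const double x = fr[p];
      const R_xlen_t base = p * max_k;
      const int n = nk[p];
      int m = -1;
      double best = R_PosInf;
      for (int k = 0; k < n; ++k) {
        const double d = x - mu[base + k];
        const double d2 = d * d / var[base + k];
        if (d2 < k2 && d2 < best) { best = d2; m = k; }
      }
      bool fg;
      if (m >= 0) {
        // classify with the weight held *before* this frame's update, so a
        // component created at frame s becomes background at the frame where
        // its accumulated weight first exceeds cf
        fg = (w[base + m] <= cf);
        for (int k = 0; k < n; ++k) w[base + k] *= (1.0 - alpha);
        w[base + m] += alpha;
        const double rho = alpha / w[base + m];
        const double d = x - mu[base + m];
        mu[base + m] += rho * d;
        double v = var[base + m] + rho * (d * d - var[base + m]);
        if (v < var_min) v = var_min;
        var[base + m] = v;
      } else {
        fg = true;
        int slot;
        if (n < max_k) {
          slot = n;
          nk[p] = n + 1;
        } else {
          slot = 0;
          for (int k = 1; k < n; ++k) if (w[base + k] < w[base + slot]) slot = k;
        }
        // scale existing weights so the mixture stays normalised
        for (int k = 0; k < nk[p]; ++k) w[base + k] *= (1.0 - alpha);
        w[base + slot] = alpha;
        mu[base + slot] = x;
        var[base + slot] = var_init;
        // renormalise exactly (replacement may have removed weight)
        double s = 0.0;
        for (int k = 0; k < nk[p]; ++k) s += w[base + k];
        for (int k = 0; k < nk[p]; ++k) w[base + k] /= s;
      }
      mask[p] = fg;
    }
    out[t] = mask;
  }
  return out;
}

// 8-connected component labelling of a binary mask. Labels are assigned in
// raster order (row by row, left to right) of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const int idx = x * H + y;
      if (!mask[idx] || lab[idx] != 0) continue;
      ++next;
      lab[idx] = next;
      stack.push_back(idx);
      while (!stack.empty()) {
        const int q = stack.back();
        stack.pop_back();
        const int qy = q % H, qx = q / H;
        for (int dx = -1; dx <= 1; ++dx) {
          const int nx = qx + dx;
          if (nx < 0 || nx >= W) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            const int ny = qy + dy;
            if (ny < 0 || ny >= H) continue;
            const int nidx = nx * H + ny;
            if (mask[nidx] && lab[nidx] == 0) {
              lab[nidx] = next;
              stack.push_back(nidx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Median filter for a binary mask: the median over an odd w x w window of
// 0/1 values is their majority. Computed with an integral image; pixels
// outside the frame count as background.
// [[Rcpp::export]]
LogicalMatrix binary_median_cpp(LogicalMatrix mask, int window) {
  const int H = mask.nrow(), W = mask.ncol();
  const int r = (window - 1) / 2;
  // integral image, (H+1) x (W+1)
  std::vector<int> ii((H + 1) * (W + 1), 0);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      ii[(x + 1) * (H + 1) + (y + 1)] =
        (mask[x * H + y] ? 1 : 0) + ii[x * (H + 1) + (y + 1)] +
        ii[(x + 1) * (H + 1) + y] - ii[x * (H + 1) + y];
  LogicalMatrix out(H, W);
  const int half = (window * window) / 2;  // majority: count > half
  for (int x = 0; x < W; ++x) {
    const int x0 = std::max(0, x - r), x1 = std::min(W - 1, x + r);
    for (int y = 0; y < H; ++y) {
      const int y0 = std::max(0, y - r), y1 = std::min(H - 1, y + r);
      const int cnt = ii[(x1 + 1) * (H + 1) + (y1 + 1)] -
                      ii[x0 * (H + 1) + (y1 + 1)] -
                      ii[(x1 + 1) * (H + 1) + y0] + ii[x0 * (H + 1) + y0];
      out[x * H + y] = cnt > half;
    }
  }
  return out;
}

// Row-wise empirical quantile (type-7) of a numeric matrix
// (pixels x frames); used for the burn-in background initialisation.
// q = 0.5 gives the temporal median; higher q is robust against dark
// organisms lingering on a pixel for up to ~q of the window.
// [[Rcpp::export]]
NumericVector row_quantiles_cpp(NumericMatrix x, double q) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(m);
  const double h = (m - 1) * q;
  const int lo = (int)std::floor(h);
  const int hi = lo + 1 < m ? lo + 1 : lo;
  const double frac = h - lo;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    std::sort(buf.begin(), buf.end());
    out[i] = buf[lo] + frac * (buf[hi] - buf[lo]);
  }
  return out;
}
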