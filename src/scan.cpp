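#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Multi-scale sliding-window evaluation of a boosted Haar cascade over one
// zone. The cascade arrives flattened: per-stage thresholds and weak counts,
// per-weak stump parameters, and one rectangle table (base-window units,
// 0-based, half-open) indexed per weak via the feature table.
//
// Feature values are contrast-normalized: raw weighted rectangle sum divided
// by (window sd * window area), matching the training-side evaluation, so a
// model trained on base-window crops transfers to rescaled windows.
//
// Returns a matrix of raw hits (x, y, size) in zone-local pixel coordinates.
// [[Rcpp::export]]
NumericMatrix scan_cascade_cpp(NumericMatrix px,
                               int window,
                               NumericVector stage_thr,
                               IntegerVector stage_nweak,
                               IntegerVector weak_feature,   // 0-based
                               NumericVector weak_thr,
                               NumericVector weak_pol,
                               NumericVector weak_alpha,
                               IntegerVector feat_offset,    // 0-based into rects
                               IntegerVector feat_nrects,
                               NumericMatrix rects,          // k x 5
                               double scale_factor,
                               double step_frac,
                               double max_window_frac,
                               double min_sd) {
  const int H = px.nrow(), W = px.ncol();
  // integral images, (H+1) x (W+1), column-major [i + j*(H+1)]
  std::vector<double> ii((H + 1) * (W + 1), 0.0), ii2((H + 1) * (W + 1), 0.0);
  for (int j = 1; j <= W; ++j) {
    double rowsum = 0.0, rowsum2 = 0.0;
    for (int i = 1; i <= H; ++i) {
      double v = px(i - 1, j - 1);
      rowsum += v; rowsum2 += v * v;
      ii[i + j * (H + 1)] = ii[i + (j - 1) * (H + 1)] + rowsum;
      ii2[i + j * (H + 1)] = ii2[i + (j - 1) * (H + 1)] + rowsum2;
    }
  }
  auto rsum = [&](const std::vector<double> &I, int x, int y, int w, int h) {
    return I[(y + h) + (x + w) * (H + 1)] - I[y + (x + w) * (H + 1)]
         - I[(y + h) + x * (H + 1)] + I[y + x * (H + 1)];
  };

  const int n_stages = stage_thr.size();
  std::vector<double> hx, hy, hs;
  int max_win = (int)std::floor(std::min(H, W) * max_window_frac);
  for (double s = 1.0; ; s *= scale_factor) {
    int win = (int)std::lround(window * s);
    if (win > max_win) break;
    double area = (double)win * (double)win;
    int step = std::max(1, (int)std::lround(win * step_frac));
    for (int y0 = 0; y0 + win <= H; y0 += step) {
      for (int x0 = 0; x0 + win <= W; x0 += step) {
        double tot = rsum(ii, x0, y0, win, win);
        double tot2 = rsum(ii2, x0, y0, win, win);
        double mu = tot / area;
        double sd = std::sqrt(std::max(tot2 / area - mu * mu, 0.0));
        if (sd < min_sd) continue;   // flat window: nothing to detect
        double denom = std::max(sd, 1e-6) * area;
        bool pass = true;
        int wk = 0;
        for (int st = 0; st < n_stages && pass; ++st) {
          double score = 0.0;
          for (int t = 0; t < stage_nweak[st]; ++t, ++wk) {
            int f = weak_feature[wk];
            double raw = 0.0;
            int off = feat_offset[f];
            for (int r = 0; r < feat_nrects[f]; ++r) {
              int rx = x0 + (int)std::lround(rects(off + r, 0) * s);
              int ry = y0 + (int)std::lround(rects(off + r, 1) * s);
              int rw = (int)std::lround(rects(off + r, 2) * s);
              int rh = (int)std::lround(rects(off + r, 3) * s);
              if (rw < 1) rw = 1;
              if (rh < 1) rh = 1;
              if (rx + rw > x0 + win) rw = x0 + win - rx;
              if (ry + rh > y0 + win) rh = y0 + win - ry;
              if (rw < 1 || rh < 1) continue;
              raw += rects(off + r, 4) * rsum(ii, rx, ry, rw, rh);
            }
            double val = raw / denom;
            double h = (weak_pol[wk] * (val - weak_thr[wk]) <= 0.0) ? 1.0 : 0.0;
            score += weak_alpha[wk] * h;
          }
          if (score < stage_thr[st]) pass = false;
        }
        if (pass) {
          hx.push_back(x0); hy.push_back(y0); hs.push_back(win);
        }
      }
    }
    if (win >= max_win) break;
  }
  NumericMatrix out(hx.size(), 3);
  for (size_t k = 0; k < hx.size(); ++k) {
    out(k, 0) = hx[k]; out(k, 1) = hy[k]; out(k, 2) = hs[k];
  }
  colnames(out) = CharacterVector::create("x", "y", "size");
  return out;
}

// Evaluate the feature table on whole square crops at their native size,
// using the identical rect-scaling and normalization as the window scanner,
// so training and scanning see the same feature distribution.
// Returns an n_crops x n_features matrix.
// [[Rcpp::export]]
NumericMatrix haar_eval_native_cpp(List crops,
                                   int window,
                                   IntegerVector feat_offset,
                                   IntegerVector feat_nrects,
                                   NumericMatrix rects) {
  const int n = crops.size();
  const int m = feat_offset.size();
  NumericMatrix out(n, m);
  for (int c = 0; c < n; ++c) {
    NumericMatrix px = crops[c];
    const int H = px.nrow(), W = px.ncol();
    const int win = std::min(H, W);
    // center-crop offset for non-square input
    const int ox = (W - win) / 2, oy = (H - win) / 2;
    double s = (double)win / (double)window;
    std::vector<double> ii((win + 1) * (win + 1), 0.0),
                        ii2((win + 1) * (win + 1), 0.0);
    for (int j = 1; j <= win; ++j) {
      double rowsum = 0.0, rowsum2 = 0.0;
      for (int i = 1; i <= win; ++i) {
        double v = px(oy + i - 1, ox + j - 1);
        rowsum += v; rowsum2 += v * v;
        ii[i + j * (win + 1)] = ii[i + (j - 1) * (win + 1)] + rowsum;
        ii2[i + j * (win + 1)] = ii2[i + (j - 1) * (win + 1)] + rowsum2;
      }
    }
    auto rsum = [&](const std::vector<double> &I, int x, int y, int w, int h) {
      return I[(y + h) + (x + w) * (win + 1)] - I[y + (x + w) * (win + 1)]
           - I[(y + h) + x * (win + 1)] + I[y + x * (win + 1)];
    };
    double area = (double)win * (double)win;
    double tot = rsum(ii, 0, 0, win, win), tot2 = rsum(ii2, 0, 0, win, win);
    double mu = tot / area;
    double sd = std::sqrt(std::max(tot2 / area - mu * mu, 0.0));
    double denom = std::max(sd, 1e-6) * area;
    for (int f = 0; f < m; ++f) {
      double raw = 0.0;
      int off = feat_offset[f];
      for (int r = 0; r < feat_nrects[f]; ++r) {
        int rx = (int)std::lround(rects(off + r, 0) * s);
        int ry = (int)std::lround(rects(off + r, 1) * s);
        int rw = (int)std::lround(rects(off + r, 2) * s);
        int rh = (int)std::lround(rects(off + r, 3) * s);
        if (rw < 1) rw = 1;
        if (rh < 1) rh = 1;
        if (rx + rw > win) rw = win - rx;
        if (ry + rh > win) rh = win - ry;
        if (rw < 1 || rh < 1) continue;
        raw += rects(off + r, 4) * rsum(ii, rx, ry, rw, rh);
      }
      out(c, f) = raw / denom;
    }
  }
  return out;
}

// Union-find grouping of raw hits (x, y, size): two hits are neighbors when
// their positions and sizes agree within eps of their mean size. Returns a
// 1-based group id per hit.
// [[Rcpp::export]]
IntegerVector group_hits_cpp(NumericMatrix hits, double eps) {
  const int n = hits.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double tol = eps * 0.5 * (hits(i, 2) + hits(j, 2));
      if (std::abs(hits(i, 0) - hits(j, 0)) <= tol &&
          std::abs(hits(i, 1) - hits(j, 1)) <= tol &&
          std::abs(hits(i, 2) - hits(j, 2)) <= tol) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = find(i) + 1;
  return out;
}
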