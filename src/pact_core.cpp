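#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Elevational weight of a point-like element for a source at polar angle
// theta (rad). model: 0 = none (aperture handled by sub-element
// integration), 1 = sinc far-field pattern of a uniform line aperture,
// 2 = Gaussian with given angular sigma (rad).
static inline double elev_weight(double sin_theta, int model,
                                 double sinc_c, double sigma_rad) {
  if (model == 0) return 1.0;
  if (model == 1) {
    double x = sinc_c * sin_theta;
    if (std::fabs(x) < 1e-12) return 1.0;
    return std::sin(x) / x;
  }
  double th = std::asin(sin_theta);
  return std::exp(-0.5 * th * th / (sigma_rad * sigma_rad));
}

// Accumulate raw N-shaped sphere waveforms (pre impulse-response).
// src: n x 3 positions (mm); elem: m x 3 element centres (mm);
// subz: elevational sub-aperture offsets (mm) averaged with equal weight.
// Output: m x nsamp pressure records sampled at fs (MHz), c = sos (mm/us).
// [[Rcpp::export]]
NumericMatrix pa_forward_spheres_cpp(NumericMatrix src, NumericVector amp,
                                     NumericVector rad, NumericMatrix elem,
                                     NumericVector subz, double sos,
                                     double fs, int nsamp, int dir_model,
                                     double sinc_c, double sigma_rad) {
  int n = src.nrow(), m = elem.nrow(), ns = subz.size();
  NumericMatrix out(m, nsamp);
  double wsub = 1.0 / ns;
  for (int e = 0; e < m; e++) {
    for (int q = 0; q < ns; q++) {
      double ex = elem(e, 0), ey = elem(e, 1), ez = elem(e, 2) + subz[q];
      for (int s = 0; s < n; s++) {
        double dx = src(s, 0) - ex, dy = src(s, 1) - ey, dz = src(s, 2) - ez;
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double a = rad[s];
        if (r <= a) continue;
        double w = wsub * elev_weight(dz / r, dir_model, sinc_c, sigma_rad);
        int k0 = (int)std::ceil((r - a) / sos * fs);
        int k1 = (int)std::floor((r + a) / sos * fs);
        if (k0 < 0) k0 = 0;
        if (k1 > nsamp - 1) k1 = nsamp - 1;
        for (int k = k0; k <= k1; k++) {
          double t = k / fs;
          out(e, k) += w * amp[s] * (r - sos * t) / (2.0 * r);
        }
      }
    }
  }
  return out;
}

// Accumulate band-limited point-source wavelets directly (already
// convolved with the Gaussian-envelope impulse response): the detected
// waveform of a sub-resolution sphere is the first time-derivative of the
// element impulse response, scaled by amp * a^3 / (3 r c^2).
// sigma_t in us, omega in rad/us.
// [[Rcpp::export]]
NumericMatrix pa_forward_points_cpp(NumericMatrix src, NumericVector amp,
                                    NumericVector rad, NumericMatrix elem,
                                    NumericVector subz, double sos,
                                    double fs, int nsamp, double sigma_t,
                                    double omega, int dir_model,
                                    double sinc_c, double sigma_rad) {
  int n = src.nrow(), m = elem.nrow(), ns = subz.size();
  NumericMatrix out(m, nsamp);
  double wsub = 1.0 / ns;
  double halfwin = 5.0 * sigma_t;
  for (int e = 0; e < m; e++) {
    for (int q = 0; q < ns; q++) {
      double ex = elem(e, 0), ey = elem(e, 1), ez = elem(e, 2) + subz[q];
      for (int s = 0; s < n; s++) {
        double dx = src(s, 0) - ex, dy = src(s, 1) - ey, dz = src(s, 2) - ez;
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-9) continue;
        double a = rad[s];
        double w = wsub * elev_weight(dz / r, dir_model, sinc_c, sigma_rad);
        double scale = w * amp[s] * a * a * a / (3.0 * r * sos * sos);
        double t0 = r / sos;
        int k0 = (int)std::ceil((t0 - halfwin) * fs);
        int k1 = (int)std::floor((t0 + halfwin) * fs);
        if (k0 < 0) k0 = 0;
        if (k1 > nsamp - 1) k1 = nsamp - 1;
        for (int k = k0; k <= k1; k++) {
          double tau = k / fs - t0;
          double env = std::exp(-0.5 * tau * tau / (sigma_t * sigma_t));
          double d = -env * (tau / (sigma_t * sigma_t) * std::cos(omega * tau)
                             + omega * std::sin(omega * tau));
          out(e, k) += scale * d;
        }
      }
    }
  }
  return out;
}

// Universal back-projection of the precomputed term B = 2 p - 2 t dp/dt.
// B: m x nsamp (one row per element record); elem: m x 3 positions; nrm:
// m x 2 in-plane inward unit normals. px/py/pz: pixel coordinates (mm).
// half_dist: maximum propagation distance used (<=0 disables truncation).
// elev_model: 0 none, 1 gaussian(sigma_rad) with hard cutoff cut_rad.
// virt_d: virtual-transducer offset along the inward normal (mm); when
// > 0 delays are |p - e'| + virt_d and angles are taken from e'.
// Returns 2 x npix: accumulated weighted values and weight sums.
// [[Rcpp::export]]
NumericMatrix ubp_backproject_cpp(NumericMatrix B, NumericMatrix elem,
                                  NumericMatrix nrm, NumericVector px,
                                  NumericVector py, NumericVector pz,
                                  double sos, double fs, double half_dist,
                                  int elev_model, double sigma_rad,
                                  double cut_rad, double virt_d) {
  int m = elem.nrow(), np = px.size(), nsamp = B.ncol();
  NumericMatrix out(2, np);
  for (int e = 0; e < m; e++) {
    double ex = elem(e, 0) + virt_d * nrm(e, 0);
    double ey = elem(e, 1) + virt_d * nrm(e, 1);
    double ez = elem(e, 2);
    for (int p = 0; p < np; p++) {
      double dx = px[p] - ex, dy = py[p] - ey, dz = pz[p] - ez;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-9) continue;
      double prop = d + virt_d;
      if (half_dist > 0 && prop > half_dist) continue;
      double w = (dx * nrm(e, 0) + dy * nrm(e, 1)) / (d * d * d);
      if (w <= 0) continue;
      if (elev_model == 1) {
        double th = std::asin(dz / d);
        if (std::fabs(th) > cut_rad) continue;
        w *= std::exp(-0.5 * th * th / (sigma_rad * sigma_rad));
      }
      out(1, p) += w;
      double s = prop / sos * fs;
      int i = (int)std::floor(s);
      if (i < 0 || i >= nsamp - 1) continue;  // out of record: contributes 0
      double f = s - i;
      out(0, p) += w * (B(e, i) * (1.0 - f) + B(e, i + 1) * f);
    }
  }
  return out;
}

// Count, for each window-centre pixel on a full grid, how many distinct
// segments intersect the square window of side w spanning
// [c - floor(w/2), c + w - 1 - floor(w/2)] (exactly w pixels, so a 2 mm
// window at 0.1 mm pixels is 20 x 20 px). seg_px: k x 2 (row, col, 1-based)
// skeleton pixels; seg_id: segment index per pixel (1-based, contiguous).
// [[Rcpp::export]]
IntegerMatrix window_segment_counts_cpp(IntegerMatrix seg_px,
                                        IntegerVector seg_id, int nrow,
                                        int ncol, int w) {
  IntegerMatrix out(nrow, ncol);
  int k = seg_px.nrow();
  int nseg = 0;
  for (int i = 0; i < k; i++) nseg = std::max(nseg, (int)seg_id[i]);
  // mark coverage one segment at a time to count each segment once
  IntegerMatrix stamp(nrow, ncol);
  std::vector<int> order(k);
  for (int i = 0; i < k; i++) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return seg_id[a] < seg_id[b]; });
  int idx = 0;
  for (int s = 1; s <= nseg; s++) {
    while (idx < k && seg_id[order[idx]] == s) {
      int r = seg_px(order[idx], 0) - 1, c = seg_px(order[idx], 1) - 1;
      int half = w / 2;
      int r0 = std::max(0, r - (w - 1 - half)), r1 = std::min(nrow - 1, r + half);
      int c0 = std::max(0, c - (w - 1 - half)), c1 = std::min(ncol - 1, c + half);
      for (int rr = r0; rr <= r1; rr++)
        for (int cc = c0; cc <= c1; cc++)
          if (stamp(rr, cc) != s) {
            stamp(rr, cc) = s;
            out(rr, cc) += 1;
          }
      idx++;
    }
  }
  return out;
}
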