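#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Edge-replicated index clamp
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Median filter with an odd square window; borders handled by edge replication.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int window) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        const int jj = clampi(j + dj, nc);
        for (int di = -h; di <= h; ++di)
          buf[k++] = img(clampi(i + di, nr), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Grayscale erosion (erode = true) or dilation with a non-flat ball
// (spherical-cap) structuring element of the given pixel radius.
// SE height at offset d is sqrt(r^2 - d^2) - r (<= 0, 0 at the centre), so
// the opening of a constant image is that constant. Edge replication.
// [[Rcpp::export]]
NumericMatrix morph_ball_cpp(const NumericMatrix& img, double radius, bool erode) {
  if (radius < 1) stop("ball radius in px must be >= 1");
  const int nr = img.nrow(), nc = img.ncol();
  const int R = (int)std::floor(radius);
  std::vector<int> oi, oj;
  std::vector<double> oh;
  for (int dj = -R; dj <= R; ++dj)
    for (int di = -R; di <= R; ++di) {
      const double d2 = (double)di * di + (double)dj * dj;
      if (d2 <= radius * radius) {
        oi.push_back(di); oj.push_back(dj);
        oh.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  const int K = (int)oi.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        const double x = img(clampi(i + oi[k], nr), clampi(j + oj[k], nc));
        if (erode) {
          const double c = x - oh[k];
          if (c < v) v = c;
        } else {
          const double c = x + oh[k];
          if (c > v) v = c;
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Concentric annulus labelling: 0 = background, 1..K from inside out,
// boundaries at radii_px (pixel units); label k for radii_px[k-1] < d <= radii_px[k].
// [[Rcpp::export]]
IntegerMatrix label_annuli_cpp(int nr, int nc, double cr, double cc,
                               const NumericVector& radii_px) {
  IntegerMatrix out(nr, nc);
  const int K = radii_px.size();
  for (int j = 0; j < nc; ++j) {
    const double dc = (j + 1) - cc;
    for (int i = 0; i < nr; ++i) {
      const double dr = (i + 1) - cr;
      const double d = std::sqrt(dr * dr + dc * dc);
      int lab = 0;
      for (int k = 0; k < K; ++k) {
        if (d <= radii_px[k]) { lab = k + 1; break; }
      }
      out(i, j) = lab;
    }
  }
  return out;
}

// Additively stamp filled discs (nuclei) of one pixel radius at the given
// 1-based centre coordinates.
// [[Rcpp::export]]
void stamp_discs_cpp(NumericMatrix img, const NumericVector& rows,
                     const NumericVector& cols, double radius_px, double amplitude) {
  const int nr = img.nrow(), nc = img.ncol();
  const int R = (int)std::ceil(radius_px);
  const double r2 = radius_px * radius_px;
  for (int k = 0; k < rows.size(); ++k) {
    const double r0 = rows[k], c0 = cols[k];
    for (int dj = -R; dj <= R; ++dj) {
      const int j = (int)std::lround(c0) + dj;
      if (j < 1 || j > nc) continue;
      for (int di = -R; di <= R; ++di) {
        const int i = (int)std::lround(r0) + di;
        if (i < 1 || i > nr) continue;
        const double dr = i - r0, dc = j - c0;
        if (dr * dr + dc * dc <= r2) img(i - 1, j - 1) += amplitude;
      }
    }
  }
}

// Rasterize a constant-width polyline stroke (rounded caps/joins: a pixel is
// painted when its centre lies within halfwidth of any segment). Returns the
// 1-based linear (column-major) indices of painted pixels restricted to
// mask == layer (layer < 0 disables clipping). No anti-aliasing.
// [[Rcpp::export]]
IntegerVector stroke_pixels_cpp(const IntegerMatrix& mask,
                                const NumericVector& xr, const NumericVector& xc,
                                double halfwidth, int layer) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int n = xr.size();
  std::vector<int> hit;
  std::vector<char> seen; // lazily sized only over the stroke bounding box
  double rmin = R_PosInf, rmax = R_NegInf, cmin = R_PosInf, cmax = R_NegInf;
  for (int k = 0; k < n; ++k) {
    rmin = std::min(rmin, xr[k]); rmax = std::max(rmax, xr[k]);
    cmin = std::min(cmin, xc[k]); cmax = std::max(cmax, xc[k]);
  }
  const int i0 = std::max(1, (int)std::floor(rmin - halfwidth));
  const int i1 = std::min(nr, (int)std::ceil(rmax + halfwidth));
  const int j0 = std::max(1, (int)std::floor(cmin - halfwidth));
  const int j1 = std::min(nc, (int)std::ceil(cmax + halfwidth));
  if (i1 < i0 || j1 < j0) return IntegerVector(0);
  const int bw = i1 - i0 + 1;
  seen.assign((size_t)bw * (j1 - j0 + 1), 0);
  const double hw2 = halfwidth * halfwidth;
  for (int s = 0; s + 1 < n || (n == 1 && s == 0); ++s) {
    const double ar = xr[s], ac = xc[s];
    const double br = (n == 1) ? ar : xr[s + 1];
    const double bc = (n == 1) ? ac : xc[s + 1];
    const int si0 = std::max(i0, (int)std::floor(std::min(ar, br) - halfwidth));
    const int si1 = std::min(i1, (int)std::ceil(std::max(ar, br) + halfwidth));
    const int sj0 = std::max(j0, (int)std::floor(std::min(ac, bc) - halfwidth));
    const int sj1 = std::min(j1, (int)std::ceil(std::max(ac, bc) + halfwidth));
    const double vr = br - ar, vc = bc - ac;
    const double L2 = vr * vr + vc * vc;
    for (int j = sj0; j <= sj1; ++j) {
      for (int i = si0; i <= si1; ++i) {
        double pr = i - ar, pc = j - ac;
        double t = (L2 > 0) ? (pr * vr + pc * vc) / L2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        const double dr = pr - t * vr, dc = pc - t * vc;
        if (dr * dr + dc * dc <= hw2) {
          const size_t b = (size_t)(i - i0) + (size_t)bw * (j - j0);
          if (!seen[b]) {
            seen[b] = 1;
            if (layer < 0 || mask(i - 1, j - 1) == layer)
              hit.push_back(i + (j - 1) * nr);
          }
        }
      }
    }
    if (n == 1) break;
  }
  return wrap(hit);
}

// Valid-centre map for an s x s square footprint (s even or odd): centre pixel
// (i, j) is valid when rows i - s/2 .. i + s - s/2 - 1 and the analogous
// columns all lie inside the raster and carry true in `ok`. Computed by two
// separable sliding-minimum passes.
// [[Rcpp::export]]
LogicalMatrix erode_square_cpp(const LogicalMatrix& ok, int side) {
  const int nr = ok.nrow(), nc = ok.ncol();
  const int lo = side / 2;          // extent above/left of centre
  const int hi = side - lo - 1;     // extent below/right of centre
  LogicalMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int j = 0; j < nc; ++j) {
    int run = 0; // trailing count of consecutive true ending at i
    for (int i = 0; i < nr; ++i) {
      run = ok(i, j) ? run + 1 : 0;
      const int c = i - hi; // centre whose window ends at i
      if (c >= 0) tmp(c, j) = (c - lo >= 0) && (run >= side);
    }
    for (int c = nr - hi; c < nr; ++c) if (c >= 0) tmp(c, j) = false;
  }
  // horizontal pass
  for (int i = 0; i < nr; ++i) {
    int run = 0;
    for (int j = 0; j < nc; ++j) {
      run = tmp(i, j) ? run + 1 : 0;
      const int c = j - hi;
      if (c >= 0) out(i, c) = (c - lo >= 0) && (run >= side);
    }
    for (int c = nc - hi; c < nc; ++c) if (c >= 0) out(i, c) = false;
  }
  return out;
}
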