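// Voxel-level kernels for the OR-PAM analysis pipeline: tube rasterisation,
// separable Gaussian PSF blur, A-line surface detection / flattening, and
// axis projections. All grids are (x, y, z) column-major with z increasing
// downward into the tissue; linear index = i + nx*(j + ny*k).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian blur, sigma per axis in voxel units. Truncated at
// 3.5 sigma; the kernel is renormalised over the in-grid support so edges
// keep local mean (no darkening at the boundary).
// One separable pass along `axis`, organised so the innermost loop always
// walks contiguous memory: the volume is viewed as [inner, len, outer]
// with `inner` the product of the dimensions preceding the axis.
static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 1e-8) return;
  int rad = (int)std::ceil(3.25 * sigma);
  std::vector<double> ker(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    ker[t + rad] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  long inner = 1;
  for (int a = 0; a < axis; ++a) inner *= n[a];
  int len = n[axis];
  long outer = ((long)nx * ny * nz) / (inner * len);
  // per-position kernel normalisation (truncated support at the edges)
  std::vector<double> norm(len);
  for (int p = 0; p < len; ++p) {
    double w = 0.0;
    int lo = std::max(0, p - rad), hi = std::min(len - 1, p + rad);
    for (int q = lo; q <= hi; ++q) w += ker[q - p + rad];
    norm[p] = 1.0 / w;
  }
  for (long o = 0; o < outer; ++o) {
    long base = o * inner * len;
    if (inner == 1) {
      for (int p = 0; p < len; ++p) {
        int lo = std::max(0, p - rad), hi = std::min(len - 1, p + rad);
        double s = 0.0;
        for (int q = lo; q <= hi; ++q) s += ker[q - p + rad] * v[base + q];
        tmp[base + p] = s * norm[p];
      }
    } else {
      std::fill(tmp.begin() + base, tmp.begin() + base + inner * len, 0.0);
      for (int p = 0; p < len; ++p) {
        int lo = std::max(0, p - rad), hi = std::min(len - 1, p + rad);
        double *__restrict dst = tmp.data() + base + (long)p * inner;
        for (int q = lo; q <= hi; ++q) {
          double w = ker[q - p + rad] * norm[p];
          const double *__restrict src = v.data() + base + (long)q * inner;
          for (long i = 0; i < inner; ++i) dst[i] += w * src[i];
        }
      }
    }
  }
  v.swap(tmp);
}

// fused amplitude + noise with clipping at zero
// [[Rcpp::export]]
NumericVector cpp_add_clip(NumericVector vol, NumericVector eps) {
  long n = vol.size();
  NumericVector out(n);
  for (long i = 0; i < n; ++i) {
    double v = vol[i] + eps[i];
    out[i] = v > 0 ? v : 0;
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long total = (long)nx * ny * nz;
  std::vector<double> v(vol.begin(), vol.end()), tmp(total);
  blur_axis(v, tmp, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(v, tmp, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(v, tmp, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(total);
  std::copy(v.begin(), v.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Rasterise tubes given as polyline centerlines in skin coordinates
// (x_um, y_um, depth_um-below-surface). The local surface depth (um below
// the grid top) shifts each A-line, so layers follow the skin profile.
// Voxel amplitude = max over tubes of intensity * indicator(dist <= radius).
// An optional epidermis sheet spans [0, sheet_thickness) below the surface.
// [[Rcpp::export]]
NumericVector cpp_render_tubes(IntegerVector dim, NumericVector spacing,
                               List centerlines, NumericVector radius,
                               NumericVector intensity,
                               NumericMatrix surface_um,
                               double sheet_intensity,
                               double sheet_thickness_um) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  long total = (long)nx * ny * nz;
  NumericVector out(total);
  out.attr("dim") = dim;

  if (sheet_intensity > 0.0 && sheet_thickness_um > 0.0) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = surface_um(i, j);
        int k0 = (int)std::ceil(s / dz - 1e-9);
        for (int k = std::max(0, k0); k < nz; ++k) {
          double d = k * dz - s;
          if (d >= sheet_thickness_um) break;
          if (d >= 0.0) out[i + (long)nx * (j + (long)ny * k)] = sheet_intensity;
        }
      }
  }

  int nves = centerlines.size();
  for (int m = 0; m < nves; ++m) {
    NumericMatrix cl = centerlines[m];
    double r = radius[m], amp = intensity[m], r2 = r * r;
    int npts = cl.nrow();
    for (int s = 0; s + 1 < npts; ++s) {
      double ax = cl(s, 0), ay = cl(s, 1), ad = cl(s, 2);
      double bx = cl(s + 1, 0), by = cl(s + 1, 1), bd = cl(s + 1, 2);
      double ux = bx - ax, uy = by - ay, ud = bd - ad;
      double L2 = ux * ux + uy * uy + ud * ud;
      int i0 = clampi((int)std::floor((std::min(ax, bx) - r) / dx), 0, nx - 1);
      int i1 = clampi((int)std::ceil((std::max(ax, bx) + r) / dx), 0, nx - 1);
      int j0 = clampi((int)std::floor((std::min(ay, by) - r) / dy), 0, ny - 1);
      int j1 = clampi((int)std::ceil((std::max(ay, by) + r) / dy), 0, ny - 1);
      double dmin = std::min(ad, bd) - r, dmax = std::max(ad, bd) + r;
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double surf = surface_um(i, j);
          int k0 = clampi((int)std::floor((dmin + surf) / dz), 0, nz - 1);
          int k1 = clampi((int)std::ceil((dmax + surf) / dz), 0, nz - 1);
          double px = i * dx, py = j * dy;
          for (int k = k0; k <= k1; ++k) {
            double pd = k * dz - surf;
            double wx = px - ax, wy = py - ay, wd = pd - ad;
            double t = L2 > 0 ? (wx * ux + wy * uy + wd * ud) / L2 : 0.0;
            t = t < 0 ? 0 : (t > 1 ? 1 : t);
            double ex = wx - t * ux, ey = wy - t * uy, ed = wd - t * ud;
            if (ex * ex + ey * ey + ed * ed <= r2) {
              long idx = i + (long)nx * (j + (long)ny * k);
              if (out[idx] < amp) out[idx] = amp;
            }
          }
        }
    }
  }
  return out;
}

// Per A-line: shallowest k (1-based) with amplitude >= frac * line max.
// Lines whose max is below floor_abs return NA.
// [[Rcpp::export]]
NumericMatrix cpp_first_crossing(NumericVector vol, IntegerVector dim,
                                 double frac, double floor_abs) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long plane = (long)nx * ny;
  // plane sweeps keep memory access sequential
  std::vector<double> mx(plane, 0.0);
  for (int k = 0; k < nz; ++k) {
    const double *__restrict src = &vol[plane * k];
    for (long t = 0; t < plane; ++t)
      if (src[t] > mx[t]) mx[t] = src[t];
  }
  std::vector<int> hit(plane, -1);
  long remaining = plane;
  for (int k = 0; k < nz && remaining > 0; ++k) {
    const double *__restrict src = &vol[plane * k];
    for (long t = 0; t < plane; ++t)
      if (hit[t] < 0 && src[t] >= frac * mx[t] && mx[t] > 0.0) {
        hit[t] = k;
        --remaining;
      }
  }
  NumericMatrix out(nx, ny);
  for (long t = 0; t < plane; ++t)
    out[t] = (mx[t] < floor_abs || mx[t] <= 0.0) ? NA_REAL : hit[t] + 1.0;
  return out;
}

// Shift each A-line so that the (fractional, 1-based) surface index lands at
// output depth index 1; linear interpolation, zero fill past the grid.
// [[Rcpp::export]]
NumericVector cpp_flatten(NumericVector vol, IntegerVector dim,
                          NumericMatrix surface_idx) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long plane = (long)nx * ny;
  NumericVector out(plane * nz);
  out.attr("dim") = dim;
  // precompute per-pixel integer shift and interpolation weight
  std::vector<int> f0(plane);
  std::vector<double> wgt(plane);
  for (long t = 0; t < plane; ++t) {
    double s0 = surface_idx[t] - 1.0; // 0-based fractional shift
    f0[t] = (int)std::floor(s0);
    wgt[t] = s0 - f0[t];
  }
  for (int k = 0; k < nz; ++k) {
    double *__restrict dst = &out[plane * k];
    for (long t = 0; t < plane; ++t) {
      long src = k + f0[t];
      if (src < 0 || src > nz - 1) continue;
      double w = wgt[t];
      double v = (w == 0.0 || src == nz - 1)
                     ? vol[plane * src + t]
                     : (1.0 - w) * vol[plane * src + t] +
                           w * vol[plane * (src + 1) + t];
      dst[t] = v;
    }
  }
  return out;
}

// 2-D median filter with window win x win (odd); the window shrinks at the
// borders. NA cells are ignored inside the window.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2d(NumericMatrix m, int win) {
  int nx = m.nrow(), ny = m.ncol(), rad = win / 2;
  NumericMatrix out(nx, ny);
  std::vector<double> buf;
  buf.reserve((size_t)win * win);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      buf.clear();
      for (int q = std::max(0, j - rad); q <= std::min(ny - 1, j + rad); ++q)
        for (int p = std::max(0, i - rad); p <= std::min(nx - 1, i + rad); ++p) {
          double v = m(p, q);
          if (!ISNAN(v)) buf.push_back(v);
        }
      if (buf.empty()) {
        out(i, j) = NA_REAL;
        continue;
      }
      size_t n = buf.size(), h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
        med = 0.5 * (med + buf[h - 1]);
      }
      out(i, j) = med;
    }
  return out;
}

// Pixelwise max over depth slab [k0, k1] (1-based, inclusive).
// [[Rcpp::export]]
NumericMatrix cpp_max_project_z(NumericVector vol, IntegerVector dim,
                                int k0, int k1) {
  int nx = dim[0], ny = dim[1], ny_ = ny;
  long step = (long)nx * ny_;
  NumericMatrix out(nx, ny_);
  for (int k = k0 - 1; k <= k1 - 1; ++k) {
    long off = step * k;
    for (long t = 0; t < step; ++t) {
      double v = vol[off + t];
      if (v > out[t]) out[t] = v;
    }
  }
  return out;
}

// Pixelwise max over the Y axis: (x, z) cross-sectional projection.
// [[Rcpp::export]]
NumericMatrix cpp_max_project_y(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nx, nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long off = (long)nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) {
        double v = vol[off + i];
        if (v > out(i, k)) out(i, k) = v;
      }
    }
  return out;
}

// suprathreshold voxel count per depth slice
// [[Rcpp::export]]
NumericVector cpp_depth_counts(NumericVector vol, IntegerVector dim,
                               double thr) {
  int nz = dim[2];
  long plane = (long)dim[0] * dim[1];
  NumericVector out(nz);
  for (int k = 0; k < nz; ++k) {
    long off = plane * k, c = 0;
    for (long t = 0; t < plane; ++t)
      if (vol[off + t] > thr) ++c;
    out[k] = (double)c;
  }
  return out;
}

// histogram bin counts matching otsu_threshold()'s binning convention:
// idx = min(floor((x - lo) / w) + 1, n_bins)
// [[Rcpp::export]]
NumericVector cpp_bincount(NumericVector v, double lo, double w, int nbins) {
  NumericVector out(nbins);
  long n = v.size();
  for (long i = 0; i < n; ++i) {
    int idx = (int)std::floor((v[i] - lo) / w);
    if (idx >= nbins) idx = nbins - 1;
    if (idx < 0) idx = 0;
    out[idx] += 1;
  }
  return out;
}

// Union mask of tube lateral projections on a supersampled grid with cell
// centres at (i + 0.5) * cell. Pure geometry: no PSF, no rendering.
// [[Rcpp::export]]
LogicalMatrix cpp_project_tubes_mask(int ncx, int ncy, double cellx,
                                     double celly, List centerlines,
                                     NumericVector radius) {
  LogicalMatrix out(ncx, ncy);
  int nves = centerlines.size();
  for (int m = 0; m < nves; ++m) {
    NumericMatrix cl = centerlines[m];
    double r = radius[m], r2 = r * r;
    int npts = cl.nrow();
    for (int s = 0; s + 1 < npts; ++s) {
      double ax = cl(s, 0), ay = cl(s, 1);
      double bx = cl(s + 1, 0), by = cl(s + 1, 1);
      double ux = bx - ax, uy = by - ay;
      double L2 = ux * ux + uy * uy;
      int i0 = clampi((int)std::floor((std::min(ax, bx) - r) / cellx - 0.5), 0, ncx - 1);
      int i1 = clampi((int)std::ceil((std::max(ax, bx) + r) / cellx + 0.5), 0, ncx - 1);
      int j0 = clampi((int)std::floor((std::min(ay, by) - r) / celly - 0.5), 0, ncy - 1);
      int j1 = clampi((int)std::ceil((std::max(ay, by) + r) / celly + 0.5), 0, ncy - 1);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          if (out(i, j)) continue;
          double px = (i + 0.5) * cellx, py = (j + 0.5) * celly;
          double wx = px - ax, wy = py - ay;
          double t = L2 > 0 ? (wx * ux + wy * uy) / L2 : 0.0;
          t = t < 0 ? 0 : (t > 1 ? 1 : t);
          double ex = wx - t * ux, ey = wy - t * uy;
          if (ex * ex + ey * ey <= r2) out(i, j) = true;
        }
    }
  }
  return out;
}
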