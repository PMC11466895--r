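#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear splat of weighted points into a stack of square images.
// px, py: 0-based continuous pixel coordinates; img_id: 1-based image index.
// Points are clamped to the grid interior; the caller counts out-of-bounds
// points beforehand.
// [[Rcpp::export]]
NumericVector splat_points_cpp(NumericVector px, NumericVector py,
                               NumericVector w, IntegerVector img_id,
                               int n, int nimg) {
  NumericVector out(static_cast<R_xlen_t>(n) * n * nimg);
  const double hi = n - 1.000001;
  R_xlen_t m = px.size();
  for (R_xlen_t k = 0; k < m; ++k) {
    double x = px[k], y = py[k];
    if (x < 0) x = 0; if (x > hi) x = hi;
    if (y < 0) y = 0; if (y > hi) y = hi;
    int ix = static_cast<int>(std::floor(x));
    int iy = static_cast<int>(std::floor(y));
    double fx = x - ix, fy = y - iy;
    R_xlen_t base = (static_cast<R_xlen_t>(img_id[k]) - 1) * n * n;
    double wk = w[k];
    out[base + ix     + static_cast<R_xlen_t>(iy)     * n] += wk * (1 - fx) * (1 - fy);
    out[base + ix + 1 + static_cast<R_xlen_t>(iy)     * n] += wk * fx       * (1 - fy);
    out[base + ix     + static_cast<R_xlen_t>(iy + 1) * n] += wk * (1 - fx) * fy;
    out[base + ix + 1 + static_cast<R_xlen_t>(iy + 1) * n] += wk * fx       * fy;
  }
  out.attr("dim") = IntegerVector::create(n, n, nimg);
  return out;
}

// Gradient of a scalar loss wrt splatted point coordinates and weights.
// grad: loss gradient wrt each image pixel (n x n x nimg).
// Returns m x 3 matrix: dL/dpx, dL/dpy, dL/dw.
// [[Rcpp::export]]
NumericMatrix gather_grad_cpp(NumericVector grad, NumericVector px,
                              NumericVector py, NumericVector w,
                              IntegerVector img_id, int n) {
  R_xlen_t m = px.size();
  NumericMatrix out(m, 3);
  const double hi = n - 1.000001;
  for (R_xlen_t k = 0; k < m; ++k) {
    double x = px[k], y = py[k];
    bool clx = false, cly = false;
    if (x < 0) { x = 0; clx = true; } if (x > hi) { x = hi; clx = true; }
    if (y < 0) { y = 0; cly = true; } if (y > hi) { y = hi; cly = true; }
    int ix = static_cast<int>(std::floor(x));
    int iy = static_cast<int>(std::floor(y));
    double fx = x - ix, fy = y - iy;
    R_xlen_t base = (static_cast<R_xlen_t>(img_id[k]) - 1) * n * n;
    double g00 = grad[base + ix     + static_cast<R_xlen_t>(iy)     * n];
    double g10 = grad[base + ix + 1 + static_cast<R_xlen_t>(iy)     * n];
    double g01 = grad[base + ix     + static_cast<R_xlen_t>(iy + 1) * n];
    double g11 = grad[base + ix + 1 + static_cast<R_xlen_t>(iy + 1) * n];
    double wk = w[k];
    // d(splat)/dx at fixed weights; zero when the point was clamped
    double dgx = clx ? 0.0 : wk * ((g10 - g00) * (1 - fy) + (g11 - g01) * fy);
    double dgy = cly ? 0.0 : wk * ((g01 - g00) * (1 - fx) + (g11 - g10) * fx);
    double dgw = g00 * (1 - fx) * (1 - fy) + g10 * fx * (1 - fy) +
                 g01 * (1 - fx) * fy       + g11 * fx * fy;
    out(k, 0) = dgx; out(k, 1) = dgy; out(k, 2) = dgw;
  }
  return out;
}

// Render a multi-class Gaussian pseudo-atom model onto a cubic grid.
// centers in Angstrom (world frame, box centre at origin); widths s and
// amplitudes a per class; d: Nc x Ng class weights.
// value(x) = sum_j sum_i d[j,i] * a[j] * exp(-|x - c_i|^2 / s_j^2)
// [[Rcpp::export]]
NumericVector render_density_cpp(NumericMatrix centers, NumericVector s,
                                 NumericVector a, NumericMatrix d,
                                 int n, double voxel, double cutoff_sd) {
  NumericVector out(static_cast<R_xlen_t>(n) * n * n);
  int ng = centers.nrow(), nc = s.size();
  double half = n / 2.0;
  for (int i = 0; i < ng; ++i) {
    double cx = centers(i, 0) / voxel + half;
    double cy = centers(i, 1) / voxel + half;
    double cz = centers(i, 2) / voxel + half;
    for (int j = 0; j < nc; ++j) {
      double w = d(j, i) * a[j];
      if (w == 0.0) continue;
      double sj = s[j];
      double rad = cutoff_sd * sj / voxel;
      int x0 = std::max(0, (int)std::ceil(cx - rad)),
          x1 = std::min(n - 1, (int)std::floor(cx + rad));
      int y0 = std::max(0, (int)std::ceil(cy - rad)),
          y1 = std::min(n - 1, (int)std::floor(cy + rad));
      int z0 = std::max(0, (int)std::ceil(cz - rad)),
          z1 = std::min(n - 1, (int)std::floor(cz + rad));
      double inv_s2 = 1.0 / (sj * sj) * voxel * voxel;
      for (int iz = z0; iz <= z1; ++iz) {
        double dz = iz - cz;
        for (int iy = y0; iy <= y1; ++iy) {
          double dy = iy - cy;
          double r2yz = dy * dy + dz * dz;
          R_xlen_t row = static_cast<R_xlen_t>(iy) * n +
                         static_cast<R_xlen_t>(iz) * n * n;
          for (int ix = x0; ix <= x1; ++ix) {
            double dx = ix - cx;
            out[row + ix] += w * std::exp(-(dx * dx + r2yz) * inv_s2);
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n);
  return out;
}

// Real-space backprojection of one image along a pose, with optional
// pull-back warp. For each voxel x (world frame) the sampling position is
// x + u(x) (u = per-voxel displacement, Angstrom); this is projected with
// rotation R plus in-plane shift and the image sampled bilinearly.
// accum is modified in place.
// [[Rcpp::export]]
void backproject_one_cpp(NumericVector img, NumericMatrix R,
                         NumericVector shift, int n, double voxel,
                         NumericVector disp, NumericVector accum) {
  double half = n / 2.0;
  bool has_disp = disp.size() > 0;
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double sx = shift[0], sy = shift[1];
  R_xlen_t nvox = static_cast<R_xlen_t>(n) * n * n;
  const double hi = n - 1.000001;
  R_xlen_t idx = 0;
  for (int iz = 0; iz < n; ++iz) {
    double z0 = (iz - half) * voxel;
    for (int iy = 0; iy < n; ++iy) {
      double y0 = (iy - half) * voxel;
      for (int ix = 0; ix < n; ++ix, ++idx) {
        double x0 = (ix - half) * voxel;
        double xs = x0, ys = y0, zs = z0;
        if (has_disp) {
          xs += disp[idx];
          ys += disp[idx + nvox];
          zs += disp[idx + 2 * nvox];
        }
        double qx = r00 * xs + r01 * ys + r02 * zs + sx;
        double qy = r10 * xs + r11 * ys + r12 * zs + sy;
        double pxx = qx / voxel + half;
        double pyy = qy / voxel + half;
        if (pxx < 0 || pxx > hi || pyy < 0 || pyy > hi) continue;
        int jx = static_cast<int>(std::floor(pxx));
        int jy = static_cast<int>(std::floor(pyy));
        double fx = pxx - jx, fy = pyy - jy;
        R_xlen_t b00 = jx + static_cast<R_xlen_t>(jy) * n;
        double v = img[b00] * (1 - fx) * (1 - fy) +
                   img[b00 + 1] * fx * (1 - fy) +
                   img[b00 + n] * (1 - fx) * fy +
                   img[b00 + n + 1] * fx * fy;
        accum[idx] += v;
      }
    }
  }
}

// Trilinear insertion of a centred 2D Fourier-plane image (e.g. CTF^2)
// into a centred 3D Fourier accumulator along the central slice
// k3d = R^T (k1, k2, 0). Frequencies in integer grid units, centre n/2.
// accum modified in place.
// [[Rcpp::export]]
void insert_slice_cpp(NumericVector plane, NumericMatrix R, int n,
                      NumericVector accum) {
  double half = n / 2.0;
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  const double hi = n - 1.000001;
  for (int j2 = 0; j2 < n; ++j2) {
    double k2 = j2 - half;
    for (int j1 = 0; j1 < n; ++j1) {
      double k1 = j1 - half;
      // R^T (k1,k2,0) = columns of R weighted
      double kx = r00 * k1 + r10 * k2;
      double ky = r01 * k1 + r11 * k2;
      double kz = r02 * k1 + r12 * k2;
      double px = kx + half, py = ky + half, pz = kz + half;
      if (px < 0 || px > hi || py < 0 || py > hi || pz < 0 || pz > hi)
        continue;
      int ix = static_cast<int>(std::floor(px));
      int iy = static_cast<int>(std::floor(py));
      int iz = static_cast<int>(std::floor(pz));
      double fx = px - ix, fy = py - iy, fz = pz - iz;
      double v = plane[j1 + static_cast<R_xlen_t>(j2) * n];
      for (int dz = 0; dz <= 1; ++dz) {
        double wz = dz ? fz : 1 - fz;
        for (int dy = 0; dy <= 1; ++dy) {
          double wy = dy ? fy : 1 - fy;
          for (int dx = 0; dx <= 1; ++dx) {
            double wx = dx ? fx : 1 - fx;
            accum[(ix + dx) + static_cast<R_xlen_t>(iy + dy) * n +
                  static_cast<R_xlen_t>(iz + dz) * n * n] += v * wx * wy * wz;
          }
        }
      }
    }
  }
}

// Trilinear resampling of a 3-component displacement field from a coarse
// cubic grid (size m, voxel voxel_c, centre m/2) onto a fine cubic grid
// (size n, voxel voxel_f, centre n/2). The base cell is clamped but the
// fractional weights are not, so affine fields extrapolate exactly.
// [[Rcpp::export]]
NumericVector upsample_field_cpp(NumericVector coarse, int m, double voxel_c,
                                 int n, double voxel_f) {
  R_xlen_t nvox = static_cast<R_xlen_t>(n) * n * n;
  R_xlen_t mvox = static_cast<R_xlen_t>(m) * m * m;
  NumericVector out(nvox * 3);
  double halfm = m / 2.0, halfn = n / 2.0;
  R_xlen_t idx = 0;
  for (int iz = 0; iz < n; ++iz) {
    double pz = ((iz - halfn) * voxel_f) / voxel_c + halfm;
    int jz = std::min(std::max((int)std::floor(pz), 0), m - 2);
    double fz = pz - jz;
    for (int iy = 0; iy < n; ++iy) {
      double py = ((iy - halfn) * voxel_f) / voxel_c + halfm;
      int jy = std::min(std::max((int)std::floor(py), 0), m - 2);
      double fy = py - jy;
      for (int ix = 0; ix < n; ++ix, ++idx) {
        double px = ((ix - halfn) * voxel_f) / voxel_c + halfm;
        int jx = std::min(std::max((int)std::floor(px), 0), m - 2);
        double fx = px - jx;
        for (int comp = 0; comp < 3; ++comp) {
          R_xlen_t off = comp * mvox;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            double wz = dz ? fz : 1 - fz;
            for (int dy = 0; dy <= 1; ++dy) {
              double wy = dy ? fy : 1 - fy;
              for (int dx = 0; dx <= 1; ++dx) {
                double wx = dx ? fx : 1 - fx;
                acc += wx * wy * wz *
                  coarse[off + (jx + dx) + static_cast<R_xlen_t>(jy + dy) * m +
                         static_cast<R_xlen_t>(jz + dz) * m * m];
              }
            }
          }
          out[idx + comp * nvox] += acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n * n * n, 3);
  return out;
}

// Trilinear sampling of a volume at world-frame positions (Angstrom).
// Positions outside the grid return 0.
// [[Rcpp::export]]
NumericVector sample_volume_cpp(NumericVector vol, int n, double voxel,
                                NumericMatrix pos) {
  R_xlen_t m = pos.nrow();
  NumericVector out(m);
  double half = n / 2.0;
  const double hi = n - 1.000001;
  for (R_xlen_t k = 0; k < m; ++k) {
    double px = pos(k, 0) / voxel + half;
    double py = pos(k, 1) / voxel + half;
    double pz = pos(k, 2) / voxel + half;
    if (px < 0 || px > hi || py < 0 || py > hi || pz < 0 || pz > hi) continue;
    int ix = (int)std::floor(px), iy = (int)std::floor(py),
        iz = (int)std::floor(pz);
    double fx = px - ix, fy = py - iy, fz = pz - iz;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      double wz = dz ? fz : 1 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          double wx = dx ? fx : 1 - fx;
          acc += wx * wy * wz *
            vol[(ix + dx) + static_cast<R_xlen_t>(iy + dy) * n +
                static_cast<R_xlen_t>(iz + dz) * n * n];
        }
      }
    }
    out[k] = acc;
  }
  return out;
}
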