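// Low-level 3D grid kernels: connected components, distance transform,
// resampling, separable filters, and the demons registration loop.
// Grids are column-major arrays with dims (nx, ny, nz); voxel centers sit at
// world = origin + index * spacing with 0-based indices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// value lookup treating outside-grid as background (0)
static inline double at0(const double* v, int i, int j, int k,
                         int nx, int ny, int nz) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[idx3(i, j, k, nx, ny)];
}

static double sample_linear(const double* v, int nx, int ny, int nz,
                            double x, double y, double z) {
  if (x < -1.0 || y < -1.0 || z < -1.0 ||
      x > nx || y > ny || z > nz) return 0.0;
  // positions within half a voxel beyond the last centre replicate the
  // border (the ceiling depth convention can probe slightly past it)
  if (x > nx - 1) x = std::min(x, (double)nx - 1);
  if (y > ny - 1) y = std::min(y, (double)ny - 1);
  if (z > nz - 1) z = std::min(z, (double)nz - 1);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        if (w > 0)
          out += w * at0(v, x0 + dx, y0 + dy, z0 + dz, nx, ny, nz);
      }
  return out;
}

static double sample_nearest(const double* v, int nx, int ny, int nz,
                             double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= nx || y >= ny || z >= nz) return 0.0;
  int i = std::min(std::max((int)std::lround(x), 0), nx - 1);
  int j = std::min(std::max((int)std::lround(y), 0), ny - 1);
  int k = std::min(std::max((int)std::lround(z), 0), nz - 1);
  return v[idx3(i, j, k, nx, ny)];
}

// ---- connected components -------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_cc_label(IntegerVector mask, IntegerVector dim,
                           int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  // neighbor offsets for the requested connectivity
  std::vector<int> ndx, ndy, ndz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
      }
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int next = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long p = idx3(i, j, k, nx, ny);
        if (!mask[p] || lab[p]) continue;
        lab[p] = ++next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          long q = stack.back(); stack.pop_back();
          int qi = q % nx, qj = (q / nx) % ny, qk = q / ((long)nx * ny);
          for (size_t m = 0; m < ndx.size(); ++m) {
            int ii = qi + ndx[m], jj = qj + ndy[m], kk = qk + ndz[m];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long r = idx3(ii, jj, kk, nx, ny);
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

// ---- Euclidean distance transform (Felzenszwalb, anisotropic) -------------

static void dt1d(const double* f, double* d, int n, double step,
                 std::vector<int>& v, std::vector<double>& z) {
  // lower envelope of parabolas; sample positions q*step
  int k = 0;
  v[0] = 0; z[0] = -DBL_MAX; z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    while (true) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = s; z[k + 1] = DBL_MAX;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// squared EDT to the zero set of f (f = 0 at features, +Inf elsewhere)
// [[Rcpp::export]]
NumericVector cpp_edt(NumericVector f, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector d = clone(f);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) buf[i] = d[idx3(i, j, k, nx, ny)];
      dt1d(buf.data(), out.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) buf[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(buf.data(), out.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = out[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) buf[k] = d[idx3(i, j, k, nx, ny)];
      dt1d(buf.data(), out.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = out[k];
    }
  return d;
}

// ---- resampling -----------------------------------------------------------

// Resample src onto a destination grid through the map y = M %*% w + t,
// where w is destination world position and y is looked up in src world.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  NumericVector sspc, NumericVector sorg,
                                  IntegerVector ddim, NumericVector dspc,
                                  NumericVector dorg, NumericVector M,
                                  NumericVector t, bool nearest) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int dx = ddim[0], dy = ddim[1], dz = ddim[2];
  NumericVector out((long)dx * dy * dz);
  const double* s = src.begin();
  for (int k = 0; k < dz; ++k) {
    double wz = dorg[2] + k * dspc[2];
    for (int j = 0; j < dy; ++j) {
      double wy = dorg[1] + j * dspc[1];
      for (int i = 0; i < dx; ++i) {
        double wx = dorg[0] + i * dspc[0];
        double yx = M[0] * wx + M[3] * wy + M[6] * wz + t[0];
        double yy = M[1] * wx + M[4] * wy + M[7] * wz + t[1];
        double yz = M[2] * wx + M[5] * wy + M[8] * wz + t[2];
        double u = (yx - sorg[0]) / sspc[0];
        double v = (yy - sorg[1]) / sspc[1];
        double w = (yz - sorg[2]) / sspc[2];
        out[idx3(i, j, k, dx, dy)] = nearest
          ? sample_nearest(s, nx, ny, nz, u, v, w)
          : sample_linear(s, nx, ny, nz, u, v, w);
      }
    }
  }
  return out;
}

// Resample src through a dense displacement: y = w + u(w), u on dest grid (µm)
// [[Rcpp::export]]
NumericVector cpp_resample_disp(NumericVector src, IntegerVector sdim,
                                NumericVector sspc, NumericVector sorg,
                                NumericVector disp, IntegerVector ddim,
                                NumericVector dspc, NumericVector dorg,
                                bool nearest) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int dx = ddim[0], dy = ddim[1], dz = ddim[2];
  long nd = (long)dx * dy * dz;
  NumericVector out(nd);
  const double* s = src.begin();
  const double* ux = disp.begin();
  const double* uy = ux + nd;
  const double* uz = uy + nd;
  for (int k = 0; k < dz; ++k)
    for (int j = 0; j < dy; ++j)
      for (int i = 0; i < dx; ++i) {
        long p = idx3(i, j, k, dx, dy);
        double yx = dorg[0] + i * dspc[0] + ux[p];
        double yy = dorg[1] + j * dspc[1] + uy[p];
        double yz = dorg[2] + k * dspc[2] + uz[p];
        double u = (yx - sorg[0]) / sspc[0];
        double v = (yy - sorg[1]) / sspc[1];
        double w = (yz - sorg[2]) / sspc[2];
        out[p] = nearest ? sample_nearest(s, nx, ny, nz, u, v, w)
                         : sample_linear(s, nx, ny, nz, u, v, w);
      }
  return out;
}

// ---- separable filters ----------------------------------------------------

static void gauss_axis(std::vector<double>& vol, int nx, int ny, int nz,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3 * sigma);
  std::vector<double> kern(2 * r + 1);
  for (int m = -r; m <= r; ++m)
    kern[m + r] = std::exp(-0.5 * m * m / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len);
  long stride[3] = {1, nx, (long)nx * ny};
  long st = stride[axis];
  for (int a = 0; a < (axis == 0 ? ny : nx); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nz); ++b) {
      long base;
      if (axis == 0)      base = idx3(0, a, b, nx, ny);
      else if (axis == 1) base = idx3(a, 0, b, nx, ny);
      else                base = idx3(a, b, 0, nx, ny);
      for (int q = 0; q < len; ++q) line[q] = vol[base + q * st];
      for (int q = 0; q < len; ++q) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
        for (int m = lo; m <= hi; ++m) {
          double w = kern[m - q + r];
          acc += w * line[m]; wsum += w;
        }
        vol[base + q * st] = acc / wsum;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector volin, IntegerVector dim,
                         NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> vol(volin.begin(), volin.end());
  gauss_axis(vol, nx, ny, nz, 0, sigma[0]);
  gauss_axis(vol, nx, ny, nz, 1, sigma[1]);
  gauss_axis(vol, nx, ny, nz, 2, sigma[2]);
  return NumericVector(vol.begin(), vol.end());
}

static void line_op(std::vector<double>& vol, int nx, int ny, int nz,
                    int axis, int r, int mode /*0 sum,1 min,2 max*/) {
  if (r <= 0) return;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len), out(len);
  long stride[3] = {1, nx, (long)nx * ny};
  long st = stride[axis];
  for (int a = 0; a < (axis == 0 ? ny : nx); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nz); ++b) {
      long base;
      if (axis == 0)      base = idx3(0, a, b, nx, ny);
      else if (axis == 1) base = idx3(a, 0, b, nx, ny);
      else                base = idx3(a, b, 0, nx, ny);
      for (int q = 0; q < len; ++q) line[q] = vol[base + q * st];
      for (int q = 0; q < len; ++q) {
        int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
        double acc = (mode == 0) ? 0.0 : line[lo];
        for (int m = lo; m <= hi; ++m) {
          if (mode == 0) acc += line[m];
          else if (mode == 1) acc = std::min(acc, line[m]);
          else acc = std::max(acc, line[m]);
        }
        out[q] = acc;
      }
      for (int q = 0; q < len; ++q) vol[base + q * st] = out[q];
    }
}

// shrinking-window box sum (divide by the analytic count in R for the mean)
// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector volin, IntegerVector dim,
                          IntegerVector radius) {
  std::vector<double> vol(volin.begin(), volin.end());
  line_op(vol, dim[0], dim[1], dim[2], 0, radius[0], 0);
  line_op(vol, dim[0], dim[1], dim[2], 1, radius[1], 0);
  line_op(vol, dim[0], dim[1], dim[2], 2, radius[2], 0);
  return NumericVector(vol.begin(), vol.end());
}

// separable min/max filter with a cube structuring element (for morphology)
// [[Rcpp::export]]
NumericVector cpp_minmax3(NumericVector volin, IntegerVector dim,
                          IntegerVector radius, bool takemax) {
  std::vector<double> vol(volin.begin(), volin.end());
  int mode = takemax ? 2 : 1;
  line_op(vol, dim[0], dim[1], dim[2], 0, radius[0], mode);
  line_op(vol, dim[0], dim[1], dim[2], 1, radius[1], mode);
  line_op(vol, dim[0], dim[1], dim[2], 2, radius[2], mode);
  return NumericVector(vol.begin(), vol.end());
}

// ---- affine similarity metric ---------------------------------------------

// mean squared difference between fixed and moving indicator channels where
// moving is probed at y = c + M (w - c) + t; both images share one grid.
// [[Rcpp::export]]
double cpp_msd_affine(NumericVector fixed, NumericVector moving,
                      IntegerVector dim, int nchan, NumericVector spacing,
                      NumericVector M, NumericVector t, NumericVector cen,
                      int step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  double acc = 0;
  long cnt = 0;
  for (int k = 0; k < nz; k += step)
    for (int j = 0; j < ny; j += step)
      for (int i = 0; i < nx; i += step) {
        double wx = i * spacing[0] - cen[0];
        double wy = j * spacing[1] - cen[1];
        double wz = k * spacing[2] - cen[2];
        double yx = cen[0] + M[0] * wx + M[3] * wy + M[6] * wz + t[0];
        double yy = cen[1] + M[1] * wx + M[4] * wy + M[7] * wz + t[1];
        double yz = cen[2] + M[2] * wx + M[5] * wy + M[8] * wz + t[2];
        double u = yx / spacing[0], v = yy / spacing[1], w = yz / spacing[2];
        long p = idx3(i, j, k, nx, ny);
        for (int c = 0; c < nchan; ++c) {
          double mv = sample_linear(moving.begin() + c * nvox, nx, ny, nz,
                                    u, v, w);
          double d = fixed[p + c * nvox] - mv;
          acc += d * d;
        }
        ++cnt;
      }
  return acc / (double)(cnt * nchan);
}

// ---- demons deformable registration ---------------------------------------

// Thirion demons on multi-channel images sharing one grid. Returns the
// displacement u (µm, fixed grid) such that moving(x + u(x)) matches fixed(x).
// [[Rcpp::export]]
NumericVector cpp_demons(NumericVector fixed, NumericVector moving,
                         IntegerVector dim, int nchan, NumericVector spacing,
                         int iters, double sigma_fluid, double sigma_elastic,
                         double max_step_vox, NumericVector u_init) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  std::vector<double> ux(nvox, 0), uy(nvox, 0), uz(nvox, 0);
  if (u_init.size() == 3 * nvox) {
    for (long p = 0; p < nvox; ++p) {
      ux[p] = u_init[p]; uy[p] = u_init[p + nvox]; uz[p] = u_init[p + 2 * nvox];
    }
  }
  // fixed-image gradients per channel (world units), central differences
  std::vector<double> gx(nvox * nchan), gy(nvox * nchan), gz(nvox * nchan);
  for (int c = 0; c < nchan; ++c) {
    const double* f = fixed.begin() + c * nvox;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long p = idx3(i, j, k, nx, ny) + c * nvox;
          gx[p] = (at0(f, i + 1, j, k, nx, ny, nz) -
                   at0(f, i - 1, j, k, nx, ny, nz)) / (2 * spacing[0]);
          gy[p] = (at0(f, i, j + 1, k, nx, ny, nz) -
                   at0(f, i, j - 1, k, nx, ny, nz)) / (2 * spacing[1]);
          gz[p] = (at0(f, i, j, k + 1, nx, ny, nz) -
                   at0(f, i, j, k - 1, nx, ny, nz)) / (2 * spacing[2]);
        }
  }
  std::vector<double> vx(nvox), vy(nvox), vz(nvox);
  double mstep = max_step_vox * spacing[0];
  // intensity-difference normalization (mean squared spacing) keeps the
  // demons step on the voxel scale regardless of physical units
  double K = (spacing[0] * spacing[0] + spacing[1] * spacing[1] +
              spacing[2] * spacing[2]) / 3.0;
  for (int it = 0; it < iters; ++it) {
    std::fill(vx.begin(), vx.end(), 0.0);
    std::fill(vy.begin(), vy.end(), 0.0);
    std::fill(vz.begin(), vz.end(), 0.0);
    for (int c = 0; c < nchan; ++c) {
      const double* f = fixed.begin() + c * nvox;
      const double* m = moving.begin() + c * nvox;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            long p = idx3(i, j, k, nx, ny);
            double px = (i * spacing[0] + ux[p]) / spacing[0];
            double py = (j * spacing[1] + uy[p]) / spacing[1];
            double pz = (k * spacing[2] + uz[p]) / spacing[2];
            double mv = sample_linear(m, nx, ny, nz, px, py, pz);
            double diff = f[p] - mv;
            long q = p + c * nvox;
            double den = gx[q] * gx[q] + gy[q] * gy[q] + gz[q] * gz[q] +
                         diff * diff / K;
            if (den > 1e-12) {
              vx[p] += diff * gx[q] / den;
              vy[p] += diff * gy[q] / den;
              vz[p] += diff * gz[q] / den;
            }
          }
    }
    // cap the per-iteration step, then fluid smoothing of the update
    for (long p = 0; p < nvox; ++p) {
      double nrm = std::sqrt(vx[p] * vx[p] + vy[p] * vy[p] + vz[p] * vz[p]);
      if (nrm > mstep) {
        double s = mstep / nrm;
        vx[p] *= s; vy[p] *= s; vz[p] *= s;
      }
    }
    if (sigma_fluid > 0) {
      gauss_axis(vx, nx, ny, nz, 0, sigma_fluid);
      gauss_axis(vx, nx, ny, nz, 1, sigma_fluid);
      gauss_axis(vx, nx, ny, nz, 2, sigma_fluid);
      gauss_axis(vy, nx, ny, nz, 0, sigma_fluid);
      gauss_axis(vy, nx, ny, nz, 1, sigma_fluid);
      gauss_axis(vy, nx, ny, nz, 2, sigma_fluid);
      gauss_axis(vz, nx, ny, nz, 0, sigma_fluid);
      gauss_axis(vz, nx, ny, nz, 1, sigma_fluid);
      gauss_axis(vz, nx, ny, nz, 2, sigma_fluid);
    }
    for (long p = 0; p < nvox; ++p) {
      ux[p] += vx[p]; uy[p] += vy[p]; uz[p] += vz[p];
    }
    // elastic smoothing of the accumulated field
    if (sigma_elastic > 0) {
      gauss_axis(ux, nx, ny, nz, 0, sigma_elastic);
      gauss_axis(ux, nx, ny, nz, 1, sigma_elastic);
      gauss_axis(ux, nx, ny, nz, 2, sigma_elastic);
      gauss_axis(uy, nx, ny, nz, 0, sigma_elastic);
      gauss_axis(uy, nx, ny, nz, 1, sigma_elastic);
      gauss_axis(uy, nx, ny, nz, 2, sigma_elastic);
      gauss_axis(uz, nx, ny, nz, 0, sigma_elastic);
      gauss_axis(uz, nx, ny, nz, 1, sigma_elastic);
      gauss_axis(uz, nx, ny, nz, 2, sigma_elastic);
    }
  }
  NumericVector out(3 * nvox);
  for (long p = 0; p < nvox; ++p) {
    out[p] = ux[p]; out[p + nvox] = uy[p]; out[p + 2 * nvox] = uz[p];
  }
  return out;
}
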