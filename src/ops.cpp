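#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
// 1D lower envelope of parabolas, sample step s (mm): d(i,j) = s^2 (i-j)^2 + f(j)
static void dt1d(std::vector<double>& f, double s2) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sft;
    while (true) {
      sft = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (sft <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sft; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = s2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// squared Euclidean distance (mm^2) to the nearest TRUE voxel, anisotropic spacing
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: infinities would poison the envelope updates (inf - inf)
  const double INF = 1e30;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? 0.0 : INF;
  std::vector<double> buf;
  // x pass
  buf.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
    for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
    dt1d(buf, spacing[0] * spacing[0]);
    for (int x = 0; x < nx; ++x) out[base + x] = buf[x];
  }
  // y pass
  buf.resize(ny);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    R_xlen_t base = (R_xlen_t)z * nx * ny + x;
    for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
    dt1d(buf, spacing[1] * spacing[1]);
    for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = buf[y];
  }
  // z pass
  buf.resize(nz);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    R_xlen_t base = (R_xlen_t)y * nx + x;
    for (int z = 0; z < nz; ++z) buf[z] = out[base + (R_xlen_t)z * nx * ny];
    dt1d(buf, spacing[2] * spacing[2]);
    for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = buf[z];
  }
  return out;
}

// ---- 26-connected component labelling ----
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < mask.size(); ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  return lab;
}

// ---- im2col / col2im for 3D convolution, cubic kernel k, padding p, stride s ----
// x: (nx, ny, nz, c) column-major; rows of the output matrix enumerate output
// positions (ox fastest), columns enumerate (kx, ky, kz, channel).
// [[Rcpp::export(name = ".cpp_im2col3")]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int k, int pad, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t npos = (R_xlen_t)ox * oy * oz;
  NumericMatrix M(npos, (R_xlen_t)k * k * k * nc);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny, sc = (R_xlen_t)nx * ny * nz;
  for (int c = 0; c < nc; ++c)
    for (int kz = 0; kz < k; ++kz) for (int ky = 0; ky < k; ++ky) for (int kx = 0; kx < k; ++kx) {
      R_xlen_t col = (R_xlen_t)kx + k * (ky + k * (kz + k * (R_xlen_t)c));
      double* out = &M(0, col);
      for (int z = 0; z < oz; ++z) {
        int iz = z * stride + kz - pad;
        for (int y = 0; y < oy; ++y) {
          int iy = y * stride + ky - pad;
          R_xlen_t r = (R_xlen_t)z * ox * oy + (R_xlen_t)y * ox;
          if (iz < 0 || iz >= nz || iy < 0 || iy >= ny) {
            for (int xo = 0; xo < ox; ++xo) out[r + xo] = 0.0;
            continue;
          }
          R_xlen_t base = c * sc + (R_xlen_t)iz * sz + (R_xlen_t)iy * sy;
          for (int xo = 0; xo < ox; ++xo) {
            int ix = xo * stride + kx - pad;
            out[r + xo] = (ix < 0 || ix >= nx) ? 0.0 : x[base + ix * sx];
          }
        }
      }
    }
  return M;
}

// scatter-add transpose of im2col: dM (npos x k^3*c) -> dx (nx, ny, nz, c)
// [[Rcpp::export(name = ".cpp_col2im3")]]
NumericVector cpp_col2im3(NumericMatrix dM, IntegerVector dims, int k, int pad, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)nx * ny * nz * nc);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny, sc = (R_xlen_t)nx * ny * nz;
  for (int c = 0; c < nc; ++c)
    for (int kz = 0; kz < k; ++kz) for (int ky = 0; ky < k; ++ky) for (int kx = 0; kx < k; ++kx) {
      R_xlen_t col = (R_xlen_t)kx + k * (ky + k * (kz + k * (R_xlen_t)c));
      const double* g = &dM(0, col);
      for (int z = 0; z < oz; ++z) {
        int iz = z * stride + kz - pad;
        if (iz < 0 || iz >= nz) continue;
        for (int y = 0; y < oy; ++y) {
          int iy = y * stride + ky - pad;
          if (iy < 0 || iy >= ny) continue;
          R_xlen_t r = (R_xlen_t)z * ox * oy + (R_xlen_t)y * ox;
          R_xlen_t base = c * sc + (R_xlen_t)iz * sz + (R_xlen_t)iy * sy;
          for (int xo = 0; xo < ox; ++xo) {
            int ix = xo * stride + kx - pad;
            if (ix >= 0 && ix < nx) dx[base + ix] += g[r + xo];
          }
        }
      }
    }
  return dx;
}

// ---- trilinear / nearest resampling onto a new voxel grid ----
// voxel centres at index*spacing (origin at the first voxel centre);
// coordinates outside the input grid are clamped to the border (edge extension).
// [[Rcpp::export(name = ".cpp_resample3")]]
NumericVector cpp_resample3(NumericVector x, IntegerVector dims, NumericVector spacing,
                            IntegerVector odims, NumericVector ospacing, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  std::vector<double> ux(ox), uy(oy), uz(oz);
  for (int i = 0; i < ox; ++i) ux[i] = std::min(std::max(i * ospacing[0] / spacing[0], 0.0), (double)(nx - 1));
  for (int i = 0; i < oy; ++i) uy[i] = std::min(std::max(i * ospacing[1] / spacing[1], 0.0), (double)(ny - 1));
  for (int i = 0; i < oz; ++i) uz[i] = std::min(std::max(i * ospacing[2] / spacing[2], 0.0), (double)(nz - 1));
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int z = 0; z < oz; ++z) {
    int z0 = (int)std::floor(uz[z]); int z1 = std::min(z0 + 1, nz - 1); double fz = uz[z] - z0;
    for (int y = 0; y < oy; ++y) {
      int y0 = (int)std::floor(uy[y]); int y1 = std::min(y0 + 1, ny - 1); double fy = uy[y] - y0;
      for (int xo = 0; xo < ox; ++xo, ++idx) {
        int x0 = (int)std::floor(ux[xo]); int x1 = std::min(x0 + 1, nx - 1); double fx = ux[xo] - x0;
        if (nearest) {
          int xi = (fx < 0.5) ? x0 : x1, yi = (fy < 0.5) ? y0 : y1, zi = (fz < 0.5) ? z0 : z1;
          out[idx] = x[(R_xlen_t)zi * sz + (R_xlen_t)yi * sy + xi];
        } else {
          double c00 = x[(R_xlen_t)z0 * sz + (R_xlen_t)y0 * sy + x0] * (1 - fx) + x[(R_xlen_t)z0 * sz + (R_xlen_t)y0 * sy + x1] * fx;
          double c10 = x[(R_xlen_t)z0 * sz + (R_xlen_t)y1 * sy + x0] * (1 - fx) + x[(R_xlen_t)z0 * sz + (R_xlen_t)y1 * sy + x1] * fx;
          double c01 = x[(R_xlen_t)z1 * sz + (R_xlen_t)y0 * sy + x0] * (1 - fx) + x[(R_xlen_t)z1 * sz + (R_xlen_t)y0 * sy + x1] * fx;
          double c11 = x[(R_xlen_t)z1 * sz + (R_xlen_t)y1 * sy + x0] * (1 - fx) + x[(R_xlen_t)z1 * sz + (R_xlen_t)y1 * sy + x1] * fx;
          out[idx] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
        }
      }
    }
  }
  return out;
}

// ---- separable 1D correlation along one axis, symmetric (mirror) padding ----
// [[Rcpp::export(name = ".cpp_filter_axis")]]
NumericVector cpp_filter_axis(NumericVector x, IntegerVector dims, NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size(), half = kl / 2;
  NumericVector out(x.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int j = 0; j < n[b2]; ++j) for (int i = 0; i < n[b1]; ++i) {
    R_xlen_t base = (R_xlen_t)i * stride[b1] + (R_xlen_t)j * stride[b2];
    for (int p = 0; p < na; ++p) {
      double acc = 0.0;
      for (int t = 0; t < kl; ++t) {
        int q = p + t - half;
        if (q < 0) q = -1 - q;
        if (q >= na) q = 2 * na - 1 - q;
        acc += kernel[t] * x[base + (R_xlen_t)q * sa];
      }
      out[base + (R_xlen_t)p * sa] = acc;
    }
  }
  return out;
}
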