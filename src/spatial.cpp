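// 3D spatial primitives: 26-connected component labeling, exact Euclidean
// distance transform (separable lower-envelope algorithm, anisotropy-aware),
// separable Gaussian smoothing and grid resampling.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Label 26-connected foreground components. Labels are assigned in order of
// each component's first voxel in the linear (column-major) scan, so the
// result is deterministic.
// [[Rcpp::export]]
List cpp_label_components_26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(mask.size());
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            const size_t u = X + (size_t)nx * (Y + (size_t)ny * Z);
            if (mask[u] && !labels[u]) {
              labels[u] = next;
              stack.push_back(u);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["n"] = next);
}

// 1D squared-distance transform (lower envelope of parabolas). Samples with
// infinite f carry no parabola; an all-infinite line stays infinite.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double step2) {
  static const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    std::fill(d.begin(), d.begin() + n, INF);
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      const double num = (f[q] + step2 * q * q) - (f[v[k]] + step2 * v[k] * v[k]);
      s = num / (2.0 * step2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = step2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in world units) from every voxel to the nearest
// seed voxel. Seeds given as a 0/1 array; spacing is mm per axis.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector seed, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(seed.size());
  for (size_t i = 0; i < n; ++i) out[i] = seed[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const size_t base = x + (size_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (size_t)nx * y];
      dt1d(f, d, ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (size_t)nx * y] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const size_t base = x + (size_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (size_t)nx * ny * z];
      dt1d(f, d, nz, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (size_t)nx * ny * z] = d[z];
    }
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

static void blur_axis(std::vector<double>& buf, const std::vector<double>& ker,
                      std::vector<double>& tmp) {
  const int n = (int)buf.size();
  const int r = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = -r; k <= r; ++k) {
      const int j = i + k;
      if (j >= 0 && j < n) acc += ker[k + r] * buf[j];
    }
    tmp[i] = acc;
  }
  buf.swap(tmp);
}

// Separable Gaussian smoothing with zero boundary; sigma in voxels per axis
// (0 disables the axis). Kernel truncated at 3 sigma and normalized.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dims,
                                NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(x);
  std::vector<std::vector<double> > kers(3);
  for (int a = 0; a < 3; ++a) {
    const double s = sigma[a];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      tot += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= tot;
    kers[a] = k;
  }
  std::vector<double> buf, tmp;
  if (!kers[0].empty()) {
    buf.resize(nx); tmp.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const size_t base = (size_t)nx * (y + (size_t)ny * z);
        for (int x1 = 0; x1 < nx; ++x1) buf[x1] = out[base + x1];
        blur_axis(buf, kers[0], tmp);
        for (int x1 = 0; x1 < nx; ++x1) out[base + x1] = buf[x1];
      }
  }
  if (!kers[1].empty()) {
    buf.resize(ny); tmp.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x1 = 0; x1 < nx; ++x1) {
        const size_t base = x1 + (size_t)nx * ny * z;
        for (int y = 0; y < ny; ++y) buf[y] = out[base + (size_t)nx * y];
        blur_axis(buf, kers[1], tmp);
        for (int y = 0; y < ny; ++y) out[base + (size_t)nx * y] = buf[y];
      }
  }
  if (!kers[2].empty()) {
    buf.resize(nz); tmp.resize(nz);
    for (int y = 0; y < ny; ++y)
      for (int x1 = 0; x1 < nx; ++x1) {
        const size_t base = x1 + (size_t)nx * y;
        for (int z = 0; z < nz; ++z) buf[z] = out[base + (size_t)nx * ny * z];
        blur_axis(buf, kers[2], tmp);
        for (int z = 0; z < nz; ++z) out[base + (size_t)nx * ny * z] = buf[z];
      }
  }
  out.attr("dim") = dims;
  return out;
}

// Resize a 3D grid to out_dims with voxel-center alignment.
// mode 0 = trilinear, 1 = nearest neighbor.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector x, IntegerVector dims,
                           IntegerVector out_dims, int mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out(Dimension(ox, oy, oz));
  const double sx = (double)nx / ox, sy = (double)ny / oy, sz = (double)nz / oz;
  for (int k = 0; k < oz; ++k) {
    const double zc = std::min(std::max((k + 0.5) * sz - 0.5, 0.0), nz - 1.0);
    for (int j = 0; j < oy; ++j) {
      const double yc = std::min(std::max((j + 0.5) * sy - 0.5, 0.0), ny - 1.0);
      for (int i = 0; i < ox; ++i) {
        const double xc = std::min(std::max((i + 0.5) * sx - 0.5, 0.0), nx - 1.0);
        double val;
        if (mode == 1) {
          const int xi = (int)std::lround(xc), yi = (int)std::lround(yc),
                    zi = (int)std::lround(zc);
          val = x[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          const int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc),
                    z0 = (int)std::floor(zc);
          const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          const double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          double c00 = x[x0 + (size_t)nx * (y0 + (size_t)ny * z0)] * (1 - fx) +
                       x[x1 + (size_t)nx * (y0 + (size_t)ny * z0)] * fx;
          double c10 = x[x0 + (size_t)nx * (y1 + (size_t)ny * z0)] * (1 - fx) +
                       x[x1 + (size_t)nx * (y1 + (size_t)ny * z0)] * fx;
          double c01 = x[x0 + (size_t)nx * (y0 + (size_t)ny * z1)] * (1 - fx) +
                       x[x1 + (size_t)nx * (y0 + (size_t)ny * z1)] * fx;
          double c11 = x[x0 + (size_t)nx * (y1 + (size_t)ny * z1)] * (1 - fx) +
                       x[x1 + (size_t)nx * (y1 + (size_t)ny * z1)] * fx;
          val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                (c01 * (1 - fy) + c11 * fy) * fz;
        }
        out[i + (size_t)ox * (j + (size_t)oy * k)] = val;
      }
    }
  }
  return out;
}
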