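// Compiled core for the rotation-based SPECT projector and the
// transmission-dependent scatter estimator.
//
// Geometry convention (shared with the R layer):
//   * volumes are (nx, ny, nz) arrays; the rotation axis is z (slice index k);
//   * for a projection angle theta the volume is rotated in the x-y plane so
//     that the detector sits beyond the j = ny-1 face; rays run along +y;
//   * a "plane" is the x-z slab at fixed y = j; planes closer to j = 0 are
//     farther from the detector.
//
// The adjoint of the bilinear rotation is the exact transpose (scatter with
// the gather weights), so <Ax, y> == <x, A^T y> up to float round-off.
// Rotation is applied slice by slice through a precomputed 2-D index/weight
// map so the inner loops stay cache-resident.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// ---------------------------------------------------------------------------
// rotation about the z axis

struct RotMap {
  std::vector<int> idx;      // 4 source indices per target (or 1 if nearest)
  std::vector<double> wgt;   // matching weights (0 when out of bounds)
  int per;                   // neighbours per target (1 or 4)
};

static RotMap build_map(int nx, int ny, double theta, bool nearest) {
  RotMap m;
  m.per = nearest ? 1 : 4;
  const int nxy = nx * ny;
  m.idx.assign((size_t)nxy * m.per, 0);
  m.wgt.assign((size_t)nxy * m.per, 0.0);
  const double c = std::cos(theta), s = std::sin(theta);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  size_t p = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i, ++p) {
      const double dx = i - cx, dy = j - cy;
      const double xs = cx + c * dx + s * dy;
      const double ys = cy - s * dx + c * dy;
      if (nearest) {
        const int ix = (int)std::lround(xs), iy = (int)std::lround(ys);
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
          m.idx[p] = ix + nx * iy;
          m.wgt[p] = 1.0;
        }
      } else {
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        const double fx = xs - x0, fy = ys - y0;
        const int xi[2] = {x0, x0 + 1}, yi[2] = {y0, y0 + 1};
        const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy};
        int q = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a, ++q) {
            if (xi[a] >= 0 && xi[a] < nx && yi[b] >= 0 && yi[b] < ny) {
              m.idx[4 * p + q] = xi[a] + nx * yi[b];
              m.wgt[4 * p + q] = wx[a] * wy[b];
            }
          }
      }
    }
  }
  return m;
}

static void apply_map(const RotMap& m, const double* src, double* dst,
                      int nxy, bool adjoint) {
  if (!adjoint) {
    if (m.per == 1) {
      for (int p = 0; p < nxy; ++p) dst[p] = m.wgt[p] * src[m.idx[p]];
    } else {
      for (int p = 0; p < nxy; ++p) {
        const size_t q = (size_t)4 * p;
        dst[p] = m.wgt[q] * src[m.idx[q]] + m.wgt[q + 1] * src[m.idx[q + 1]] +
                 m.wgt[q + 2] * src[m.idx[q + 2]] +
                 m.wgt[q + 3] * src[m.idx[q + 3]];
      }
    }
  } else {
    if (m.per == 1) {
      for (int p = 0; p < nxy; ++p) dst[m.idx[p]] += m.wgt[p] * src[p];
    } else {
      for (int p = 0; p < nxy; ++p) {
        const size_t q = (size_t)4 * p;
        const double v = src[p];
        if (v == 0.0) continue;
        dst[m.idx[q]] += m.wgt[q] * v;
        dst[m.idx[q + 1]] += m.wgt[q + 1] * v;
        dst[m.idx[q + 2]] += m.wgt[q + 2] * v;
        dst[m.idx[q + 3]] += m.wgt[q + 3] * v;
      }
    }
  }
}

static void rotate_into(const cube& v, cube& out, double theta, bool adjoint,
                        bool nearest) {
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (std::abs(theta) < 1e-12) {
    out = v;
    return;
  }
  out.zeros();
  const RotMap m = build_map(nx, ny, theta, nearest);
  const int nxy = nx * ny;
  for (int k = 0; k < nz; ++k)
    apply_map(m, v.slice(k).memptr(), out.slice(k).memptr(), nxy, adjoint);
}

// [[Rcpp::export]]
arma::cube rotate_xy_cpp(const arma::cube& v, double theta,
                         bool adjoint = false, bool nearest = false) {
  cube out(v.n_rows, v.n_cols, v.n_slices);
  rotate_into(v, out, theta, adjoint, nearest);
  return out;
}

// ---------------------------------------------------------------------------
// per-plane (x, z) Gaussian blur with a per-plane sigma (voxel units)

static vec gauss_kernel(double sigma_vox) {
  const int h = std::max(1, (int)std::ceil(4.0 * sigma_vox));
  vec k(2 * h + 1);
  for (int t = -h; t <= h; ++t)
    k(t + h) = std::exp(-0.5 * (double)(t * t) / (sigma_vox * sigma_vox));
  k /= arma::accu(k);
  return k;
}

// zero-padded gather convolution of the columns (dim 0) of p
static void conv_cols(const mat& in, mat& out, const vec& k) {
  const int h = ((int)k.n_elem - 1) / 2;
  const int n = in.n_rows, nc = in.n_cols;
  for (int c = 0; c < nc; ++c) {
    const double* src = in.colptr(c);
    double* dst = out.colptr(c);
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
      double acc = 0.0;
      for (int t = lo; t <= hi; ++t) acc += src[t] * k(h + t - i);
      dst[i] = acc;
    }
  }
}

static void blur_plane(mat& p, const vec& k, mat& tmp) {
  conv_cols(p, tmp, k);                     // along x
  mat tt = tmp.t();                         // transpose so z is contiguous
  mat t2(tt.n_rows, tt.n_cols);
  conv_cols(tt, t2, k);                     // along z
  p = t2.t();
}

static void blur_planes_inplace(cube& v, const vec& sigma_vox) {
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  mat p(nx, nz), tmp(nx, nz);
  for (int j = 0; j < ny; ++j) {
    const double s = sigma_vox(j);
    if (s < 1e-3) continue;
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) p(i, k) = v(i, j, k);
    const vec ker = gauss_kernel(s);
    blur_plane(p, ker, tmp);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) v(i, j, k) = p(i, k);
  }
}

// ---------------------------------------------------------------------------
// attenuation path lengths in the rotated frame
//
// path(i,j,k) = dcm * (0.5 * mu(i,j,k) + sum_{j' > j} mu(i,j',k))
// (half-voxel self-attenuation; detector beyond the j = ny-1 face)

// [[Rcpp::export]]
arma::cube atten_path_cpp(const arma::cube& murot, double dcm) {
  const int nx = murot.n_rows, ny = murot.n_cols, nz = murot.n_slices;
  cube path(nx, ny, nz);
  std::vector<double> beyond((size_t)nx);
  for (int k = 0; k < nz; ++k) {
    std::fill(beyond.begin(), beyond.end(), 0.0);
    for (int j = ny - 1; j >= 0; --j) {
      for (int i = 0; i < nx; ++i) {
        const double m = murot(i, j, k);
        path(i, j, k) = dcm * (0.5 * m + beyond[i]);
        beyond[i] += m;
      }
    }
  }
  return path;
}

// ---------------------------------------------------------------------------
// one-angle forward / back projection

// [[Rcpp::export]]
arma::mat forward_one_cpp(const arma::cube& vol, const arma::cube& w,
                          const arma::vec& sigma_vox, double theta,
                          bool nearest = false) {
  cube r(vol.n_rows, vol.n_cols, vol.n_slices);
  rotate_into(vol, r, theta, false, nearest);
  blur_planes_inplace(r, sigma_vox);
  const int nx = r.n_rows, ny = r.n_cols, nz = r.n_slices;
  mat proj(nx, nz, arma::fill::zeros);
  const bool haveW = (w.n_elem == r.n_elem);
  for (int k = 0; k < nz; ++k) {
    double* pk = proj.colptr(k);
    for (int j = 0; j < ny; ++j) {
      const double* rk = r.slice_colptr(k, j);
      if (haveW) {
        const double* wk = w.slice_colptr(k, j);
        for (int i = 0; i < nx; ++i) pk[i] += rk[i] * wk[i];
      } else {
        for (int i = 0; i < nx; ++i) pk[i] += rk[i];
      }
    }
  }
  return proj;
}

// [[Rcpp::export]]
arma::cube back_one_cpp(const arma::mat& proj, const arma::cube& w,
                        const arma::vec& sigma_vox, double theta,
                        int nx, int ny, int nz, bool nearest = false) {
  cube t(nx, ny, nz);
  const bool haveW = ((int)w.n_elem == nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    const double* pk = proj.colptr(k);
    for (int j = 0; j < ny; ++j) {
      double* tk = t.slice_colptr(k, j);
      if (haveW) {
        const double* wk = w.slice_colptr(k, j);
        for (int i = 0; i < nx; ++i) tk[i] = pk[i] * wk[i];
      } else {
        for (int i = 0; i < nx; ++i) tk[i] = pk[i];
      }
    }
  }
  blur_planes_inplace(t, sigma_vox);
  cube out(nx, ny, nz);
  rotate_into(t, out, theta, true, nearest);
  return out;
}

// ---------------------------------------------------------------------------
// separable 3-D Gaussian convolution (zero padded, kernel sums to one)

// [[Rcpp::export]]
arma::cube gauss3_cpp(const arma::cube& v, double sigma_vox) {
  if (sigma_vox < 1e-3) return v;
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  const vec k = gauss_kernel(sigma_vox);
  const int h = ((int)k.n_elem - 1) / 2;
  cube a(nx, ny, nz), b(nx, ny, nz);
  // along x (contiguous)
  for (int kk = 0; kk < nz; ++kk)
    for (int j = 0; j < ny; ++j) {
      const double* src = v.slice_colptr(kk, j);
      double* dst = a.slice_colptr(kk, j);
      for (int i = 0; i < nx; ++i) {
        const int lo = std::max(0, i - h), hi = std::min(nx - 1, i + h);
        double acc = 0.0;
        for (int t = lo; t <= hi; ++t) acc += src[t] * k(h + t - i);
        dst[i] = acc;
      }
    }
  // along y (stride nx within a slice)
  for (int kk = 0; kk < nz; ++kk) {
    const mat sl(const_cast<double*>(a.slice_colptr(kk, 0)), nx, ny, false);
    mat out(b.slice_colptr(kk, 0), nx, ny, false, true);
    mat st = sl.t();
    mat ot(ny, nx);
    conv_cols(st, ot, k);
    out = ot.t();
  }
  // along z (stride nx*ny)
  const int nxy = nx * ny;
  const double* bp = b.memptr();
  double* ap = a.memptr();
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const int base = i + nx * j;
      for (int kk = 0; kk < nz; ++kk) {
        const int lo = std::max(0, kk - h), hi = std::min(nz - 1, kk + h);
        double acc = 0.0;
        for (int t = lo; t <= hi; ++t)
          acc += bp[base + (size_t)nxy * t] * k(h + t - kk);
        ap[base + (size_t)nxy * kk] = acc;
      }
    }
  return a;
}

// ---------------------------------------------------------------------------
// TDSC: per-plane direct convolution with depth-dependent kernels (sources
// restricted to the attenuating medium), then voxel-wise scaling by the
// scatter-to-primary fraction, then a plain sum along the detector
// direction (no attenuation, no PSF blur).

// [[Rcpp::export]]
arma::mat tdsc_angle_cpp(const arma::cube& rot, const arma::cube& path,
                         const arma::cube& medium, const List& kernels,
                         const IntegerVector& kidx,
                         double sfA, double sfB, double sfG,
                         double src_eps = 1e-14) {
  const int nx = rot.n_rows, ny = rot.n_cols, nz = rot.n_slices;
  mat proj(nx, nz, arma::fill::zeros);
  // padded accumulation buffer sized for the largest kernel
  int hmax = 0;
  std::vector<mat> kmats(kernels.size());
  for (int q = 0; q < kernels.size(); ++q) {
    kmats[q] = as<mat>(kernels[q]);
    hmax = std::max(hmax, ((int)kmats[q].n_rows - 1) / 2);
  }
  mat buf(nx + 2 * hmax, nz + 2 * hmax);
  for (int j = 0; j < ny; ++j) {
    const int ki = kidx[j];
    if (ki <= 0) continue;  // plane outside the attenuating support
    const mat& K = kmats[ki - 1];
    const int h = ((int)K.n_rows - 1) / 2;
    const int ks = K.n_rows;
    buf.zeros();
    bool any = false;
    for (int k = 0; k < nz; ++k) {
      const double* rk = rot.slice_colptr(k, j);
      const double* mk = medium.slice_colptr(k, j);
      for (int i = 0; i < nx; ++i) {
        const double v = rk[i];
        if (mk[i] <= 0.0 || std::abs(v) < src_eps) continue;
        any = true;
        // scatter-add v * K centred at (i, k) into the padded buffer
        const int bi = i + hmax - h, bk = k + hmax - h;
        for (int c = 0; c < ks; ++c) {
          const double* kc = K.colptr(c);
          double* bc = buf.colptr(bk + c) + bi;
          for (int r = 0; r < ks; ++r) bc[r] += v * kc[r];
        }
      }
    }
    if (!any) continue;
    for (int k = 0; k < nz; ++k) {
      const double* pk = path.slice_colptr(k, j);
      double* out = proj.colptr(k);
      const double* bc = buf.colptr(k + hmax) + hmax;
      for (int i = 0; i < nx; ++i) {
        const double sf = sfA - sfB * std::exp(-sfG * pk[i]) - 1.0;
        out[i] += bc[i] * (sf > 0.0 ? sf : 0.0);
      }
    }
  }
  return proj;
}

// ---------------------------------------------------------------------------
// 26-connected component containing a seed voxel

// [[Rcpp::export]]
LogicalVector component_from_seed_cpp(const LogicalVector& mask,
                                      const IntegerVector& dim, int seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  if (seed < 0 || seed >= mask.size() || !mask[seed]) return out;
  std::vector<char> seen(mask.size(), 0);
  std::queue<int> q;
  q.push(seed);
  seen[seed] = 1;
  while (!q.empty()) {
    const int idx = q.front();
    q.pop();
    out[idx] = true;
    const int k = idx / (nx * ny);
    const int j = (idx - k * nx * ny) / nx;
    const int i = idx % nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const int nidx = ii + nx * (jj + ny * kk);
          if (!seen[nidx] && mask[nidx]) {
            seen[nidx] = 1;
            q.push(nidx);
          }
        }
  }
  return out;
}
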