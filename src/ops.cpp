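#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Sample a 3D volume at continuous 0-based voxel coordinates.
// mode 0 = trilinear, 1 = nearest. Points outside [0, n-1] per axis get `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericMatrix idx, int mode, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z)) { out[p] = fill; continue; }
    if (mode == 1) {
      long i = (long)std::lround(x), j = (long)std::lround(y), k = (long)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) out[p] = fill;
      else out[p] = v[lin3((int)i, (int)j, (int)k, nx, ny)];
    } else {
      // tolerate float round-off at the exact volume border
      const double eps = 1e-6;
      if (x < -eps || y < -eps || z < -eps ||
          x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) {
        out[p] = fill; continue;
      }
      if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
      if (x > nx - 1) x = nx - 1;
      if (y > ny - 1) y = ny - 1;
      if (z > nz - 1) z = nz - 1;
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
      if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
      if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = i0 + 1 < nx ? i0 + 1 : i0;
      int j1 = j0 + 1 < ny ? j0 + 1 : j0;
      int k1 = k0 + 1 < nz ? k0 + 1 : k0;
      double c000 = v[lin3(i0, j0, k0, nx, ny)], c100 = v[lin3(i1, j0, k0, nx, ny)];
      double c010 = v[lin3(i0, j1, k0, nx, ny)], c110 = v[lin3(i1, j1, k0, nx, ny)];
      double c001 = v[lin3(i0, j0, k1, nx, ny)], c101 = v[lin3(i1, j0, k1, nx, ny)];
      double c011 = v[lin3(i0, j1, k1, nx, ny)], c111 = v[lin3(i1, j1, k1, nx, ny)];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Connected-component labeling of a binary 3D mask.
// connectivity: 1 = faces (6), 2 = faces+edges (18), 3 = full (26).
// Labels are assigned in raster-scan order (x fastest) of each component's
// first voxel, starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0 || s > connectivity) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p0 = lin3(i, j, k, nx, ny);
        if (mask[p0] == 0 || lab[p0] != 0) continue;
        // raster order here is k,j,i outer-to-inner which differs from the
        // linear-index order (x fastest); re-scan below guarantees x-fastest
        // ordering because lin3 order and this triple loop order coincide.
        lab[p0] = ++next;
        q.push(p0);
        while (!q.empty()) {
          R_xlen_t p = q.front(); q.pop();
          int pi = (int)(p % nx), pj = (int)((p / nx) % ny), pk = (int)(p / ((R_xlen_t)nx * ny));
          for (size_t m = 0; m < dxs.size(); ++m) {
            int ii = pi + dxs[m], jj = pj + dys[m], kk = pk + dzs[m];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t pp = lin3(ii, jj, kk, nx, ny);
            if (mask[pp] != 0 && lab[pp] == 0) { lab[pp] = next; q.push(pp); }
          }
        }
      }
  return lab;
}

// Separable Gaussian smoothing, truncated at 3 sigma, border-renormalized.
// sigma is in voxels, one value per axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth3(NumericVector vol, IntegerVector dim,
                                   NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(vol.begin(), vol.end()), tmp(n);
  const int nd[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    for (int t = -r; t <= r; ++t) ker[t + r] = std::exp(-0.5 * t * t / (s * s));
    R_xlen_t stride = 1;
    for (int a = 0; a < ax; ++a) stride *= nd[a];
    int len = nd[ax];
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // decompose line id into the coordinates of the two non-`ax` axes
      R_xlen_t l = line;
      int co[3];
      for (int a = 0; a < 3; ++a) {
        if (a == ax) { co[a] = 0; continue; }
        co[a] = (int)(l % nd[a]);
        l /= nd[a];
      }
      R_xlen_t b = lin3(co[0], co[1], co[2], nx, ny);
      for (int t = 0; t < len; ++t) {
        double acc = 0, wsum = 0;
        int lo = t - r < 0 ? 0 : t - r;
        int hi = t + r > len - 1 ? len - 1 : t + r;
        for (int u = lo; u <= hi; ++u) {
          double w = ker[u - t + r];
          acc += w * cur[b + (R_xlen_t)u * stride];
          wsum += w;
        }
        tmp[b + (R_xlen_t)t * stride] = acc / wsum;
      }
    }
    cur.swap(tmp);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Displacement of a Gaussian radial-basis warp: d(p) = sum_k a_k exp(-|p-c_k|^2 / 2 sd^2)
// [[Rcpp::export]]
NumericMatrix cpp_rbf_displacement(NumericMatrix pts, NumericMatrix centers,
                                   NumericMatrix amps, double sd) {
  const R_xlen_t n = pts.nrow();
  const int K = centers.nrow();
  NumericMatrix out(n, 3);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);
  const double cut2 = 12.25 * sd * sd; // 3.5 sigma
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double dx = 0, dy = 0, dz = 0;
    for (int k = 0; k < K; ++k) {
      double rx = x - centers(k, 0), ry = y - centers(k, 1), rz = z - centers(k, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 > cut2) continue;
      double w = std::exp(-r2 * inv2s2);
      dx += w * amps(k, 0); dy += w * amps(k, 1); dz += w * amps(k, 2);
    }
    out(p, 0) = dx; out(p, 1) = dy; out(p, 2) = dz;
  }
  return out;
}

// Invert the forward RBF warp f(x) = x + d(x) by per-point fixed-point
// iteration: given p, solve x with f(x) = p, i.e. x <- p - d(x).
// [[Rcpp::export]]
NumericMatrix cpp_rbf_inverse(NumericMatrix pts, NumericMatrix centers,
                              NumericMatrix amps, double sd, double tol, int maxit) {
  const R_xlen_t n = pts.nrow();
  const int K = centers.nrow();
  NumericMatrix out(n, 3);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);
  const double cut2 = 12.25 * sd * sd;
  for (R_xlen_t p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double x = px, y = py, z = pz;
    for (int it = 0; it < maxit; ++it) {
      double dx = 0, dy = 0, dz = 0;
      for (int k = 0; k < K; ++k) {
        double rx = x - centers(k, 0), ry = y - centers(k, 1), rz = z - centers(k, 2);
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 > cut2) continue;
        double w = std::exp(-r2 * inv2s2);
        dx += w * amps(k, 0); dy += w * amps(k, 1); dz += w * amps(k, 2);
      }
      double nx = px - dx, ny = py - dy, nz = pz - dz;
      double mv = std::fabs(nx - x) + std::fabs(ny - y) + std::fabs(nz - z);
      x = nx; y = ny; z = nz;
      if (mv < tol) break;
    }
    out(p, 0) = x; out(p, 1) = y; out(p, 2) = z;
  }
  return out;
}

// Binary dilation with the given connectivity, repeated `iterations` times.
// [[Rcpp::export]]
IntegerVector cpp_binary_dilate(IntegerVector mask, IntegerVector dim,
                                int connectivity, int iterations) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0 || s > connectivity) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  std::vector<int> cur(mask.begin(), mask.end()), nxt(n);
  for (int it = 0; it < iterations; ++it) {
    nxt = cur;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = lin3(i, j, k, nx, ny);
          if (cur[p] == 0) continue;
          for (size_t m = 0; m < dxs.size(); ++m) {
            int ii = i + dxs[m], jj = j + dys[m], kk = k + dzs[m];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            nxt[lin3(ii, jj, kk, nx, ny)] = 1;
          }
        }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}

// Central-difference spatial gradient (per mm) of a 3D volume.
// Returns an n-voxel x 3 matrix in linear-index order.
// [[Rcpp::export]]
NumericMatrix cpp_gradient3(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, 3);
  const double *v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = lin3(i, j, k, nx, ny);
        int ip = i + 1 < nx ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < ny ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < nz ? k + 1 : k, km = k > 0 ? k - 1 : k;
        out(p, 0) = (v[lin3(ip, j, k, nx, ny)] - v[lin3(im, j, k, nx, ny)]) /
                    ((ip - im) * spacing[0]);
        out(p, 1) = (v[lin3(i, jp, k, nx, ny)] - v[lin3(i, jm, k, nx, ny)]) /
                    ((jp - jm) * spacing[1]);
        out(p, 2) = (v[lin3(i, j, kp, nx, ny)] - v[lin3(i, j, km, nx, ny)]) /
                    ((kp - km) * spacing[2]);
      }
  return out;
}
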