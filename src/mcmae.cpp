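// Low-level numerical kernels: 3D convolution via im2col/GEMM, 3D
// connected-component labelling, threshold-free cluster enhancement,
// and trilinear interpolation.  All single-threaded and deterministic.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Volumes are stored as N x C matrices (N = X*Y*Z voxels, column-major
// x-fastest, matching an R array with dim c(X, Y, Z, C)).

// Neighbourhood matrix in N x K layout (K = k^3 * C): column k holds one
// shifted copy of the volume, so each write is a contiguous x-strip.
static arma::mat im2col3(const arma::mat& x, int X, int Y, int Z, int k) {
  const int C = x.n_cols;
  const int N = X * Y * Z;
  const int p = (k - 1) / 2;      // same-padding radius
  const int K = k * k * k * C;
  arma::mat cols(N, K, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int dz = -p; dz <= p; ++dz) {
      for (int dy = -p; dy <= p; ++dy) {
        for (int dx = -p; dx <= p; ++dx) {
          double* dst = cols.colptr(col++);
          int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < Z; ++z) {
            int zz = z + dz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              int yy = y + dy;
              if (yy < 0 || yy >= Y) continue;
              const double* s = src + (size_t)(zz * Y + yy) * X + dx;
              double* d = dst + (size_t)(z * Y + y) * X;
              std::copy(s + x0, s + x1, d + x0);
            }
          }
        }
      }
    }
  }
  return cols;
}

static arma::mat col2im3(const arma::mat& cols, int X, int Y, int Z,
                         int C, int k) {
  const int p = (k - 1) / 2;
  arma::mat out(X * Y * Z, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    double* dst = out.colptr(c);
    for (int dz = -p; dz <= p; ++dz) {
      for (int dy = -p; dy <= p; ++dy) {
        for (int dx = -p; dx <= p; ++dx) {
          const double* src = cols.colptr(col++);
          int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < Z; ++z) {
            int zz = z + dz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              int yy = y + dy;
              if (yy < 0 || yy >= Y) continue;
              double* d = dst + (size_t)(zz * Y + yy) * X + dx;
              const double* s = src + (size_t)(z * Y + y) * X;
              for (int xx = x0; xx < x1; ++xx)
                d[xx] += s[xx];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& x, int X, int Y, int Z,
                         const arma::mat& W, const arma::vec& b, int k) {
  arma::mat cols = im2col3(x, X, Y, Z, k);   // N x K
  arma::mat y = cols * W.t();                // N x Cout
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& x, int X, int Y, int Z,
                    const arma::mat& W, const arma::mat& gout, int k) {
  // gout: N x Cout
  arma::mat cols = im2col3(x, X, Y, Z, k);   // N x K
  arma::mat dW = gout.t() * cols;            // Cout x K
  arma::vec db = arma::sum(gout, 0).t();
  arma::mat dcols = gout * W;                // N x K
  arma::mat dx = col2im3(dcols, X, Y, Z, x.n_cols, k);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

static void conn_offsets(int connectivity, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, int X, int Y,
                                   int Z, int connectivity) {
  const int N = X * Y * Z;
  IntegerVector lab(N, 0);
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < N; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % X, y = (v / X) % Y, z = v / (X * Y);
      for (auto& o : off) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
          continue;
        int w = nx + X * (ny + Y * nz);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// TFCE for a non-negative map: sum over midpoint thresholds h of
// e(v,h)^E * h^H * dh, e(v,h) = size of the component containing v at
// threshold h.  Thresholds are processed in descending order with an
// incremental union-find, so each voxel is activated once and clusters
// only ever merge.  Sign handling (negative lobes) is in the R wrapper.
// [[Rcpp::export]]
NumericVector cpp_tfce_nonneg(const NumericVector& map, int X, int Y, int Z,
                              double E, double H, int n_steps,
                              int connectivity) {
  const int N = X * Y * Z;
  NumericVector out(N, 0.0);
  double mx = 0.0;
  for (int i = 0; i < N; ++i) mx = std::max(mx, map[i]);
  if (mx <= 0.0) return out;
  const double dh = mx / n_steps;
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  std::vector<int> order;
  order.reserve(N);
  for (int i = 0; i < N; ++i) if (map[i] > 0) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return map[a] > map[b]; });
  std::vector<int> parent(N, -1), csize(N, 0), stamp(N, -1);
  std::vector<double> powcache(N);
  std::vector<int> active;
  active.reserve(order.size());
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  size_t ptr = 0;
  for (int s = n_steps; s >= 1; --s) {
    const double h = (s - 0.5) * dh;
    while (ptr < order.size() && map[order[ptr]] >= h) {
      int v = order[ptr++];
      parent[v] = v; csize[v] = 1;
      active.push_back(v);
      int x = v % X, y = (v / X) % Y, z = v / (X * Y);
      for (auto& o : off) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
          continue;
        int w = nx + X * (ny + Y * nz);
        if (parent[w] < 0) continue;         // neighbour not yet active
        int rv = find(v), rw = find(w);
        if (rv == rw) continue;
        if (csize[rv] < csize[rw]) std::swap(rv, rw);
        parent[rw] = rv;
        csize[rv] += csize[rw];
      }
    }
    const double hH = std::pow(h, H) * dh;
    for (int v : active) {
      int r = find(v);
      if (stamp[r] != s) { stamp[r] = s; powcache[r] = std::pow((double)csize[r], E); }
      out[v] += powcache[r] * hH;
    }
  }
  return out;
}

// Trilinear interpolation at separable output coordinates (0-based voxel
// indices into the input grid); coordinates are clamped to the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& x, int X, int Y, int Z,
                            const NumericVector& xi, const NumericVector& yi,
                            const NumericVector& zi) {
  const int nx = xi.size(), ny = yi.size(), nz = zi.size();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<int> x0(nx), y0(ny), z0(nz);
  std::vector<double> fx(nx), fy(ny), fz(nz);
  auto prep = [](const NumericVector& ci, int n, int dim,
                 std::vector<int>& i0, std::vector<double>& fr) {
    for (int i = 0; i < n; ++i) {
      double c = std::min(std::max(ci[i], 0.0), (double)(dim - 1));
      int lo = (int)std::floor(c);
      if (lo > dim - 2) lo = std::max(0, dim - 2);
      i0[i] = lo;
      fr[i] = (dim == 1) ? 0.0 : c - lo;
    }
  };
  prep(xi, nx, X, x0, fx); prep(yi, ny, Y, y0, fy); prep(zi, nz, Z, z0, fz);
  size_t o = 0;
  for (int k = 0; k < nz; ++k) {
    int zl = z0[k]; double wz = fz[k];
    int zh = std::min(zl + 1, Z - 1);
    for (int j = 0; j < ny; ++j) {
      int yl = y0[j]; double wy = fy[j];
      int yh = std::min(yl + 1, Y - 1);
      for (int i = 0; i < nx; ++i, ++o) {
        int xl = x0[i]; double wx = fx[i];
        int xh = std::min(xl + 1, X - 1);
        auto at = [&](int a, int b, int c) {
          return x[(size_t)a + X * ((size_t)b + (size_t)Y * c)];
        };
        double c00 = at(xl, yl, zl) * (1 - wx) + at(xh, yl, zl) * wx;
        double c10 = at(xl, yh, zl) * (1 - wx) + at(xh, yh, zl) * wx;
        double c01 = at(xl, yl, zh) * (1 - wx) + at(xh, yl, zh) * wx;
        double c11 = at(xl, yh, zh) * (1 - wx) + at(xh, yh, zh) * wx;
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        out[o] = c0 * (1 - wz) + c1 * wz;
      }
    }
  }
  return out;
}
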