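#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Dense 3D convolution kernels for the autodiff tape.  Arrays are column-major
// with layout (x, y, z, channel); weights are (kx, ky, kz, c_in, c_out).
// Stride 1, zero padding that preserves spatial shape; kernel sizes must be odd.

static inline R_xlen_t idx4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * (z + (R_xlen_t)nz * c));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  if (wd[3] != ci) stop("conv3d: input channels (%d) do not match kernel (%d)", ci, wd[3]);
  if (kx % 2 == 0 || ky % 2 == 0 || kz % 2 == 0) stop("conv3d: kernel sizes must be odd");
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  NumericVector out((R_xlen_t)nx * ny * nz * co);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int oc = 0; oc < co; ++oc) {
    for (int ic = 0; ic < ci; ++ic) {
      for (int k3 = 0; k3 < kz; ++k3) {
        const int dz = k3 - pz;
        for (int k2 = 0; k2 < ky; ++k2) {
          const int dy = k2 - py;
          for (int k1 = 0; k1 < kx; ++k1) {
            const int dx = k1 - px;
            const double wv = w[k1 + (R_xlen_t)kx * (k2 + (R_xlen_t)ky * (k3 + (R_xlen_t)kz * (ic + (R_xlen_t)ci * oc)))];
            if (wv == 0.0) continue;
            const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
            const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
            const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                const double* xr = xp + idx4(x0 + dx, y + dy, z + dz, ic, nx, ny, nz);
                double* orow = op + idx4(x0, y, z, oc, nx, ny, nz);
                for (int xq = x0; xq < x1; ++xq) *orow++ += wv * *xr++;
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return out;
}

// gradient wrt input: correlation of upstream gradient with the flipped kernel
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector gy, IntegerVector xd,
                                   NumericVector w, IntegerVector wd) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  NumericVector gx((R_xlen_t)nx * ny * nz * ci);
  const double* gp = gy.begin();
  double* op = gx.begin();
  for (int oc = 0; oc < co; ++oc) {
    for (int ic = 0; ic < ci; ++ic) {
      for (int k3 = 0; k3 < kz; ++k3) {
        const int dz = k3 - pz;
        for (int k2 = 0; k2 < ky; ++k2) {
          const int dy = k2 - py;
          for (int k1 = 0; k1 < kx; ++k1) {
            const int dx = k1 - px;
            const double wv = w[k1 + (R_xlen_t)kx * (k2 + (R_xlen_t)ky * (k3 + (R_xlen_t)kz * (ic + (R_xlen_t)ci * oc)))];
            if (wv == 0.0) continue;
            // out[v] (gx, channel ic) accumulates wv * gy[v - d, oc]
            const int z0 = std::max(0, dz), z1 = std::min(nz, nz + dz);
            const int y0 = std::max(0, dy), y1 = std::min(ny, ny + dy);
            const int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                const double* gr = gp + idx4(x0 - dx, y - dy, z - dz, oc, nx, ny, nz);
                double* orow = op + idx4(x0, y, z, ic, nx, ny, nz);
                for (int xq = x0; xq < x1; ++xq) *orow++ += wv * *gr++;
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  return gx;
}

// gradient wrt weights
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_weight(NumericVector x, IntegerVector xd,
                                    NumericVector gy, IntegerVector wd) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  NumericVector gw((R_xlen_t)kx * ky * kz * ci * co);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  for (int oc = 0; oc < co; ++oc) {
    for (int ic = 0; ic < ci; ++ic) {
      for (int k3 = 0; k3 < kz; ++k3) {
        const int dz = k3 - pz;
        for (int k2 = 0; k2 < ky; ++k2) {
          const int dy = k2 - py;
          for (int k1 = 0; k1 < kx; ++k1) {
            const int dx = k1 - px;
            double acc = 0.0;
            const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
            const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
            const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                const double* xr = xp + idx4(x0 + dx, y + dy, z + dz, ic, nx, ny, nz);
                const double* gr = gp + idx4(x0, y, z, oc, nx, ny, nz);
                for (int xq = x0; xq < x1; ++xq) acc += *xr++ * *gr++;
              }
            }
            gw[k1 + (R_xlen_t)kx * (k2 + (R_xlen_t)ky * (k3 + (R_xlen_t)kz * (ic + (R_xlen_t)ci * oc)))] = acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(kx, ky, kz, ci, co);
  return gw;
}

// Connected components of a binary mask under 26-connectivity (BFS labelling).
// Returns an integer array of component labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components_26(LogicalVector mask, IntegerVector d) {
  const int nx = d[0], ny = d[1], nz = d[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            const int u = xx + nx * (yy + ny * zz);
            if (mask[u] && lab[u] == 0) { lab[u] = next; q.push(u); }
          }
        }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// For each row of `a` (n x 3 voxel coordinates), the Euclidean distance to the
// nearest row of `b`, with coordinates scaled per-axis by `spacing`.
// [[Rcpp::export]]
NumericVector cpp_nn_distances(NumericMatrix a, NumericMatrix b, NumericVector spacing) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0) * sx, ay = a(i, 1) * sy, az = a(i, 2) * sz;
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0) * sx, dy = ay - b(j, 1) * sy, dz = az - b(j, 2) * sz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
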