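#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel kernel value at offset x (grid cells) for width W and shape
// parameter beta; zero outside |x| > W/2.
static inline double kb(double x, double halfw, double beta) {
  const double t = 1.0 - (x / halfw) * (x / halfw);
  if (t <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(t), 0.0, 1.0);
}

// Scatter weighted complex samples onto an M^3 Cartesian k-grid with a
// separable Kaiser-Bessel kernel. Sample positions u are in grid index
// units (cycles per voxel times M), centred on 0; the grid is returned in
// FFT wrap order, i.e. index = (round(u) mod M).
// [[Rcpp::export]]
ComplexVector cpp_grid_kspace(NumericMatrix u, ComplexVector vals,
                              NumericVector w, int M, double width,
                              double beta) {
  const int n = u.nrow();
  if (vals.size() != n || w.size() != n)
    stop("vals and w must have one entry per sample");
  ComplexVector grid(static_cast<R_xlen_t>(M) * M * M);
  std::vector<double> gre(static_cast<size_t>(M) * M * M, 0.0);
  std::vector<double> gim(static_cast<size_t>(M) * M * M, 0.0);
  const double halfw = width / 2.0;
  const double *ux = &u(0, 0), *uy = &u(0, 1), *uz = &u(0, 2);
  std::vector<double> kx(8), ky(8), kz(8);
  for (int i = 0; i < n; ++i) {
    const double sr = w[i] * vals[i].r, si = w[i] * vals[i].i;
    if (sr == 0.0 && si == 0.0) continue;
    const int x0 = static_cast<int>(std::ceil(ux[i] - halfw));
    const int y0 = static_cast<int>(std::ceil(uy[i] - halfw));
    const int z0 = static_cast<int>(std::ceil(uz[i] - halfw));
    const int x1 = static_cast<int>(std::floor(ux[i] + halfw));
    const int y1 = static_cast<int>(std::floor(uy[i] + halfw));
    const int z1 = static_cast<int>(std::floor(uz[i] + halfw));
    const int nx = x1 - x0 + 1, ny = y1 - y0 + 1, nz = z1 - z0 + 1;
    if (nx <= 0 || ny <= 0 || nz <= 0) continue;
    kx.resize(nx); ky.resize(ny); kz.resize(nz);
    for (int a = 0; a < nx; ++a) kx[a] = kb(x0 + a - ux[i], halfw, beta);
    for (int b = 0; b < ny; ++b) ky[b] = kb(y0 + b - uy[i], halfw, beta);
    for (int c = 0; c < nz; ++c) kz[c] = kb(z0 + c - uz[i], halfw, beta);
    for (int c = 0; c < nz; ++c) {
      int zc = (z0 + c) % M; if (zc < 0) zc += M;
      const size_t zoff = static_cast<size_t>(zc) * M * M;
      for (int b = 0; b < ny; ++b) {
        int yb = (y0 + b) % M; if (yb < 0) yb += M;
        const size_t yoff = zoff + static_cast<size_t>(yb) * M;
        const double kyz = ky[b] * kz[c];
        for (int a = 0; a < nx; ++a) {
          int xa = (x0 + a) % M; if (xa < 0) xa += M;
          const double kk = kx[a] * kyz;
          gre[yoff + xa] += sr * kk;
          gim[yoff + xa] += si * kk;
        }
      }
    }
  }
  for (R_xlen_t j = 0; j < grid.size(); ++j) {
    grid[j].r = gre[j];
    grid[j].i = gim[j];
  }
  grid.attr("dim") = IntegerVector::create(M, M, M);
  return grid;
}

// 6-connected binary dilation of a 3D logical volume, n iterations.
// [[Rcpp::export]]
LogicalVector cpp_dilate6(LogicalVector mask, IntegerVector dims, int n_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> cur(mask.begin(), mask.end()), nxt(cur.size());
  for (int it = 0; it < n_iter; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const size_t id = x + static_cast<size_t>(nx) * (y + static_cast<size_t>(ny) * z);
          int v = cur[id];
          if (!v) {
            if (x > 0      && cur[id - 1]) v = 1;
            else if (x < nx - 1 && cur[id + 1]) v = 1;
            else if (y > 0      && cur[id - nx]) v = 1;
            else if (y < ny - 1 && cur[id + nx]) v = 1;
            else if (z > 0      && cur[id - static_cast<size_t>(nx) * ny]) v = 1;
            else if (z < nz - 1 && cur[id + static_cast<size_t>(nx) * ny]) v = 1;
          }
          nxt[id] = v;
        }
    cur.swap(nxt);
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dims;
  return out;
}
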