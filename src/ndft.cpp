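#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact non-uniform discrete Fourier transforms used by the acquisition
// simulator and by the slow reference reconstruction. k-space points are in
// cycles per voxel; voxel coordinates are in voxel units relative to the
// grid centre (N-1)/2, so phases are exp(-2*pi*i * k . r).

// [[Rcpp::export]]
ComplexVector cpp_ndft_forward(NumericMatrix kpts, NumericMatrix coords,
                               NumericVector vals) {
  const int n = kpts.nrow(), m = coords.nrow();
  if (vals.size() != m) stop("vals must have one entry per coordinate");
  ComplexVector out(n);
  const double *kx = &kpts(0, 0), *ky = &kpts(0, 1), *kz = &kpts(0, 2);
  const double *rx = &coords(0, 0), *ry = &coords(0, 1), *rz = &coords(0, 2);
  for (int i = 0; i < n; ++i) {
    double re = 0.0, im = 0.0;
    const double a = -2.0 * M_PI * kx[i];
    const double b = -2.0 * M_PI * ky[i];
    const double c = -2.0 * M_PI * kz[i];
    for (int j = 0; j < m; ++j) {
      const double ph = a * rx[j] + b * ry[j] + c * rz[j];
      re += vals[j] * std::cos(ph);
      im += vals[j] * std::sin(ph);
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

// Adjoint: image at given coordinates from weighted samples,
// sum_i w_i s_i exp(+2*pi*i * k_i . r). Reference reconstruction.
// [[Rcpp::export]]
ComplexVector cpp_ndft_adjoint(NumericMatrix kpts, ComplexVector svals,
                               NumericVector w, NumericMatrix coords) {
  const int n = kpts.nrow(), m = coords.nrow();
  if (svals.size() != n || w.size() != n)
    stop("sample values and weights must have one entry per k-point");
  ComplexVector out(m);
  std::vector<double> ore(m, 0.0), oim(m, 0.0);
  const double *kx = &kpts(0, 0), *ky = &kpts(0, 1), *kz = &kpts(0, 2);
  const double *rx = &coords(0, 0), *ry = &coords(0, 1), *rz = &coords(0, 2);
  for (int i = 0; i < n; ++i) {
    const double sr = w[i] * svals[i].r, si = w[i] * svals[i].i;
    const double a = 2.0 * M_PI * kx[i];
    const double b = 2.0 * M_PI * ky[i];
    const double c = 2.0 * M_PI * kz[i];
    for (int j = 0; j < m; ++j) {
      const double ph = a * rx[j] + b * ry[j] + c * rz[j];
      const double cs = std::cos(ph), sn = std::sin(ph);
      ore[j] += sr * cs - si * sn;
      oim[j] += sr * sn + si * cs;
    }
  }
  for (int j = 0; j < m; ++j) { out[j].r = ore[j]; out[j].i = oim[j]; }
  return out;
}
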