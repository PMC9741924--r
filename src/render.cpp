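#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render one RF echo frame by coherent summation of Gabor SSF values at the
// scatterer positions. The echo sample at (z_k, x_l) is
//   g[k,l] = sum_n a_n * h_G(x_n - x_kl)
// with h_G separable in x, y, z. Each scatterer contributes only inside a
// truncated +/- trunc*sigma footprint per axis; scatterers further than
// trunc*sigma_y_amp from the scan plane are skipped entirely.
//
// Grid: axial samples z_k = z0 + (k-1)*dz (k = 1..K, rows),
//       lateral samples x_l = x0 + (l-1)*dx (l = 1..L, columns).
// [[Rcpp::export(name = ".render_frame")]]
NumericMatrix render_frame(NumericMatrix pos, NumericVector amp,
                           int K, int L, double z0, double dz,
                           double x0, double dx,
                           double u0, double phi,
                           double sigma_x, double sigma_y_amp, double sigma_z,
                           double trunc_sd = 3.5) {
  NumericMatrix g(K, L);
  const int n = pos.nrow();
  const double inv2sx2 = 0.5 / (sigma_x * sigma_x);
  const double inv2sy2 = 0.5 / (sigma_y_amp * sigma_y_amp);
  const double inv2sz2 = 0.5 / (sigma_z * sigma_z);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) *
                             (2.0 * sigma_x * sigma_x) * sigma_z);
  const double rx = trunc_sd * sigma_x;
  const double ry = trunc_sd * sigma_y_amp;
  const double rz = trunc_sd * sigma_z;
  const double two_pi_u0 = 2.0 * M_PI * u0;

  std::vector<double> wz(K);  // per-scatterer axial profile buffer

  for (int i = 0; i < n; ++i) {
    const double xs = pos(i, 0), ys = pos(i, 1), zs = pos(i, 2);
    if (std::fabs(ys) > ry) continue;
    // lateral index range touching the footprint
    int l_lo = (int)std::ceil((xs - rx - x0) / dx);
    int l_hi = (int)std::floor((xs + rx - x0) / dx);
    if (l_lo < 0) l_lo = 0;
    if (l_hi > L - 1) l_hi = L - 1;
    if (l_lo > l_hi) continue;
    int k_lo = (int)std::ceil((zs - rz - z0) / dz);
    int k_hi = (int)std::floor((zs + rz - z0) / dz);
    if (k_lo < 0) k_lo = 0;
    if (k_hi > K - 1) k_hi = K - 1;
    if (k_lo > k_hi) continue;

    const double a = amp[i] * norm * std::exp(-ys * ys * inv2sy2);
    for (int k = k_lo; k <= k_hi; ++k) {
      // SSF argument is scatterer-minus-sample: dz_rel = z_n - z_k
      const double dzr = zs - (z0 + k * dz);
      wz[k] = std::sin(two_pi_u0 * dzr + phi) *
              std::exp(-dzr * dzr * inv2sz2);
    }
    for (int l = l_lo; l <= l_hi; ++l) {
      const double dxr = xs - (x0 + l * dx);
      const double wx = a * std::exp(-dxr * dxr * inv2sx2);
      double* col = &g(0, l);
      for (int k = k_lo; k <= k_hi; ++k) col[k] += wx * wz[k];
    }
  }
  return g;
}
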