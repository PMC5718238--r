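#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted-packet Monte Carlo walk on the 2-D tissue grid.
//
// Photons carry a full 3-D direction vector but only its in-plane (y, z)
// projection advances the position; the out-of-plane component is kept so
// the direction statistics of Henyey-Greenstein scattering stay unbiased
// (for a broad field, packets leave and enter the plane at equal rates).
// RNG is R's own stream (unif_rand) so set.seed() reproduces runs exactly.

static inline double hg_cos_theta(double g, double R) {
  if (g == 0.0) return 2.0 * R - 1.0;          // isotropic inverse-CDF
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * R);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(IntegerMatrix class_map,   // [ny, nz], codes 1..3
                      NumericMatrix mua,         // [600, 3] per wavelength bin, per class code
                      NumericMatrix mus,
                      double g,
                      double n_surface,
                      double cell_size,
                      double beam_y0, double beam_y1,
                      NumericVector spec_cdf,    // length 600, cumulative weights
                      int n_photons,
                      double w_min,
                      bool deposit_residual,
                      bool mirror_lateral) {
  const int ny = class_map.nrow(), nz = class_map.ncol();
  const double Ly = ny * cell_size, Lz = nz * cell_size;
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (beam_y0 < 0 || beam_y1 > Ly || beam_y1 <= beam_y0)
    stop("beam aperture outside the domain");

  NumericMatrix numabs(ny, nz);
  double t_spec = 0, t_drefl = 0, t_trans = 0, t_abs = 0, t_resid = 0;

  // specular reflection at the air--epidermis boundary, normal incidence
  const double rsp = std::pow((n_surface - 1.0) / (n_surface + 1.0), 2.0);
  const int nlam = spec_cdf.size();

  RNGScope scope;
  for (int ip = 0; ip < n_photons; ++ip) {
    // wavelength bin by inverse CDF
    double u = unif_rand();
    int lo = 0, hi = nlam - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (spec_cdf[mid] <= u) lo = mid + 1; else hi = mid;
    }
    const int il = lo;

    // launch: uniform over the aperture, normal incidence, downward
    double y = beam_y0 + (beam_y1 - beam_y0) * unif_rand();
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double W = 1.0 - rsp;
    t_spec += rsp;

    double dep_sum = 0.0;
    long steps = 0;
    for (;;) {
      if (++steps > 20000000L) stop("photon step cap exceeded");
      int iy = (int)(y / cell_size);
      int iz = (int)(z / cell_size);
      if (iy < 0) iy = 0; else if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; else if (iz >= nz) iz = nz - 1;
      int cc = class_map(iy, iz) - 1;
      double mut = mua(il, cc) + mus(il, cc);
      if (!(mut > 0)) stop("non-scattering, non-absorbing cell encountered");

      double r = unif_rand();
      while (r <= 0.0) r = unif_rand();
      double s = -std::log(r) / mut;
      y += uy * s;
      z += uz * s;
      if (!std::isfinite(y) || !std::isfinite(z) || !std::isfinite(W))
        stop("non-finite photon state (simulation bug)");

      if (z < 0.0) { t_drefl += W; break; }                 // escaped the surface
      if (mirror_lateral) {
        // broad-field symmetry: reflect at the lateral domain faces
        while (y < 0.0 || y >= Ly) {
          if (y < 0.0) y = -y; else y = 2.0 * Ly - y;
          uy = -uy;
        }
      }
      if (z >= Lz || y < 0.0 || y >= Ly) { t_trans += W; break; }

      // deposit with the end-point cell's coefficients
      iy = (int)(y / cell_size);
      iz = (int)(z / cell_size);
      cc = class_map(iy, iz) - 1;
      double ma = mua(il, cc), ms = mus(il, cc);
      double dW = W * ma / (ma + ms);
      numabs(iy, iz) += dW;
      dep_sum += dW;
      W -= dW;

      if (W < w_min) {                                      // 1/100-weight rule
        if (deposit_residual) { numabs(iy, iz) += W; dep_sum += W; }
        else t_resid += W;
        break;
      }

      // redirect: HG deflection + uniform azimuth
      double ct = hg_cos_theta(g, unif_rand());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
      }
    }
    t_abs += dep_sum;
  }

  double n = (double)n_photons;
  return List::create(
    _["numabs"] = numabs,
    _["specular_reflected"] = t_spec / n,
    _["diffuse_reflected"] = t_drefl / n,
    _["transmitted"] = t_trans / n,
    _["absorbed"] = t_abs / n,
    _["terminated_residual"] = t_resid / n
  );
}
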