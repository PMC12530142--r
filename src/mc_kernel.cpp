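// Time-resolved Monte Carlo random walk in a homogeneous cuboid.
//
// Geometry: cube of side `cube_side` cm; z axis points down into the medium,
// the top face is z = 0 with the source at the origin (isotropic launch into
// the lower hemisphere). The top face has a refractive-index mismatch
// (probabilistic Fresnel reflection, specular); side and bottom faces absorb.
// Scattering: exponential free path with mu_s = mu_s' / (1 - g) and
// Henyey-Greenstein deflection. Absorption is NOT applied here: the walk
// depends only on scattering, so runs with different mu_a but the same seed
// traverse identical trajectories; the caller applies the continuous
// absorption weight exp(-mu_a * pathlength) when binning. Photons whose
// in-medium pathlength exceeds the acquisition window are terminated
// ("expired"): they can never contribute to the time-resolved signal.
//
// Uses R's RNG (caller controls reproducibility with set.seed()).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double fresnel_R(double ci, double n1, double n2) {
  // unpolarized Fresnel reflectance, cosine of incidence ci in (0, 1]
  double s2 = (1.0 - ci * ci) * (n1 / n2) * (n1 / n2); // sin^2(theta_t)
  if (s2 >= 1.0) return 1.0;                           // total internal refl.
  double ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_walk_cpp")]]
List mc_walk_cpp(double mu_s, double g, double n_medium, double n_outside,
                 double cube_side, NumericVector det_radii,
                 double annulus_width, double max_path, int n_photons) {
  const double half = cube_side / 2.0;
  const int nd = det_radii.size();
  std::vector<double> r_lo(nd), r_hi(nd);
  for (int d = 0; d < nd; ++d) {
    r_lo[d] = det_radii[d] - annulus_width / 2.0;
    r_hi[d] = det_radii[d] + annulus_width / 2.0;
  }
  std::vector<int> ev_det;
  std::vector<double> ev_path;
  double w_top = 0.0, w_side = 0.0, w_expired = 0.0;

  RNGScope scope;
  for (int p = 0; p < n_photons; ++p) {
    double x = 0.0, y = 0.0, z = 0.0, path = 0.0;
    // isotropic launch into the medium: uz uniform on (0, 1]
    double uz = unif_rand();
    double phi = 2.0 * M_PI * unif_rand();
    double sr = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double ux = sr * std::cos(phi), uy = sr * std::sin(phi);

    bool alive = true;
    while (alive) {
      double step = -std::log(unif_rand()) / mu_s;
      while (step > 0.0 && alive) {
        if (uz < 0.0) {
          double d_top = -z / uz; // distance to the z = 0 plane
          if (d_top <= step) {
            x += ux * d_top; y += uy * d_top; path += d_top; z = 0.0;
            step -= d_top;
            double R = (n_medium == n_outside)
                         ? 0.0 : fresnel_R(-uz, n_medium, n_outside);
            if (unif_rand() > R) { // transmitted: photon escapes the top face
              if (path > max_path) {
                w_expired += 1.0;
              } else {
                w_top += 1.0;
                double r = std::sqrt(x * x + y * y);
                for (int d = 0; d < nd; ++d) {
                  if (r >= r_lo[d] && r < r_hi[d]) {
                    ev_det.push_back(d + 1);
                    ev_path.push_back(path);
                    break;
                  }
                }
              }
              alive = false;
            } else {
              uz = -uz; // specular reflection back into the medium
            }
            continue;
          }
        }
        x += ux * step; y += uy * step; z += uz * step; path += step;
        step = 0.0;
        if (z > cube_side || std::abs(x) > half || std::abs(y) > half) {
          w_side += 1.0; // absorbing side/bottom faces
          alive = false;
        } else if (path > max_path) {
          w_expired += 1.0; // beyond the acquisition window
          alive = false;
        }
      }
      if (!alive) break;
      // Henyey-Greenstein scattering
      double ct;
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double psi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::abs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nz = -st * cp * den + uz * ct;
        ux = nx; uy = ny; uz = nz;
      }
    }
  }
  return List::create(
    _["det"] = wrap(ev_det), _["path"] = wrap(ev_path),
    _["w_top"] = w_top, _["w_side"] = w_side, _["w_expired"] = w_expired);
}
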