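#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted-photon Monte Carlo transport from a flat-tip fiber in a homogeneous
// medium, tallied on a cylindrical (r, z) grid. Absorption is scored at each
// interaction site (MCML-style: dw = w * mu_a / mu_t), fluence follows from
// deposited energy / (mu_a * voxel volume). The grid boundary is absorbing:
// weight crossing it is scored as escaped. Russian roulette terminates
// low-weight photons; its kills and compensating gains are tallied separately
// so the energy balance closes exactly per run.

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - frac * frac) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
List mc_transport_cpp(double mu_a, double mu_s, double g, double n_medium,
                      double fiber_radius, double na,
                      double r_max, double z_min, double z_max,
                      double dr, double dz, int n_photons,
                      double roulette_threshold, double roulette_survival) {
  if (mu_a <= 0 || mu_s < 0 || g <= -1 || g >= 1 || n_medium < 1)
    stop("non-physical optical properties");
  if (na <= 0 || na >= n_medium || fiber_radius <= 0)
    stop("non-physical fiber specification");
  if (n_photons < 1) stop("n_photons must be >= 1");

  const int nr = (int)std::lround((r_max - 0.0) / dr);
  const int nz = (int)std::lround((z_max - z_min) / dz);
  NumericMatrix deposit(nr, nz); // absorbed weight per voxel

  const double mu_t = mu_a + mu_s;
  const double cos_half = std::cos(std::asin(na / n_medium));
  double absorbed = 0.0, escaped = 0.0;
  double roulette_killed = 0.0, roulette_gained = 0.0;

  RNGScope scope; // draws from R's RNG: seeded determinism via set.seed()

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch: uniform over the fiber disk, direction uniform in the NA cone
    double rl = fiber_radius * std::sqrt(unif_rand());
    double phl = 2.0 * M_PI * unif_rand();
    double x = rl * std::cos(phl), y = rl * std::sin(phl), z = 0.0;
    double cz = cos_half + (1.0 - cos_half) * unif_rand();
    double sz = std::sqrt(1.0 - cz * cz);
    double phd = 2.0 * M_PI * unif_rand();
    double ux = sz * std::cos(phd), uy = sz * std::sin(phd), uz = cz;
    double w = 1.0;

    for (;;) {
      double s = -std::log(unif_rand()) / mu_t;
      x += ux * s; y += uy * s; z += uz * s;
      double r = std::sqrt(x * x + y * y);
      if (r >= r_max || z < z_min || z >= z_max) { escaped += w; break; }

      double dw = w * mu_a / mu_t;
      int ir = (int)(r / dr);
      int iz = (int)((z - z_min) / dz);
      deposit(ir, iz) += dw;
      absorbed += dw;
      w -= dw;
      if (w <= 0.0) break; // pure absorber: everything deposited

      if (w < roulette_threshold) {
        if (unif_rand() < roulette_survival) {
          roulette_gained += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          roulette_killed += w;
          break;
        }
      }

      // scatter: Henyey-Greenstein polar angle, uniform azimuth
      double ct = hg_cos(g, unif_rand());
      double st = std::sqrt(1.0 - ct * ct);
      double psi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp; nuy = st * sp; nuz = ct * (uz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nuz = -st * cp * den + uz * ct;
      }
      ux = nux; uy = nuy; uz = nuz;
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }

  return List::create(
    _["deposit"] = deposit,
    _["absorbed"] = absorbed,
    _["escaped"] = escaped,
    _["roulette_killed"] = roulette_killed,
    _["roulette_gained"] = roulette_gained,
    _["launched"] = (double)n_photons,
    _["nr"] = nr, _["nz"] = nz
  );
}
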