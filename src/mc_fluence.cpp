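// Voxel Monte Carlo photon transport for 2D tissue cross-sections.
//
// Standard hop/drop/spin scheme: exponential free paths with fractional
// propagation across voxel boundaries, absorption weighting (drop w*mua/mut
// at each interaction), Henyey-Greenstein scattering, Russian roulette
// termination. The grid is a (ny, nz) cross-section; photons move in 3D but
// optical properties are invariant along x, so only (y, z) index the medium.
// z is depth with the illuminated surface at z = 0. The z boundaries are
// absorbing; the lateral y boundary is absorbing or periodic.
//
// Two estimators are accumulated per voxel: absorbed weight (deposition)
// and track length (weight * path length, in weight*cm). The R wrapper
// converts these to fluence normalized to unit surface-incident fluence.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

namespace {

inline double runif64(std::mt19937_64& rng) {
  // 53-bit uniform in [0, 1); avoids std::uniform_real_distribution,
  // whose output sequence is implementation-defined
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

inline double hg_cost(std::mt19937_64& rng, double g) {
  if (std::fabs(g) < 1e-6) return 2.0 * runif64(rng) - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * runif64(rng));
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  return std::max(-1.0, std::min(1.0, c));
}

inline void spin(std::mt19937_64& rng, double g,
                 double& ux, double& uy, double& uz) {
  double cost = hg_cost(rng, g);
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * runif64(rng);
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0 ? cost : -cost);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nz = -sint * cosp * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

} // namespace

// [[Rcpp::export(name = ".mc_fluence_cpp")]]
List mc_fluence_cpp(NumericMatrix mu_a, NumericMatrix mu_s, NumericMatrix g,
                    double voxel_cm, int n_photons, int illumination,
                    int periodic_y, double roulette_weight,
                    double roulette_survive, double seed1, double seed2) {
  const int ny = mu_a.nrow(), nz = mu_a.ncol();
  const double W = ny * voxel_cm, D = nz * voxel_cm;
  const double eps = 1e-9;
  NumericMatrix absorbed(ny, nz), track(ny, nz);
  double tot_abs = 0.0, tot_esc = 0.0, tot_kill = 0.0, tot_gain = 0.0;

  std::seed_seq sseq{(uint64_t)seed1, (uint64_t)seed2};
  std::mt19937_64 rng(sseq);

  for (int ph = 0; ph < n_photons; ++ph) {
    double w = 1.0;
    double y = (illumination == 0) ? 0.5 * W : runif64(rng) * W;
    double z = eps;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double tau = -std::log(runif64(rng) + 1e-300);
    bool alive = true;
    while (alive) {
      int iy = (int)std::floor(y / voxel_cm);
      int iz = (int)std::floor(z / voxel_cm);
      if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
      double ma = mu_a(iy, iz), ms = mu_s(iy, iz);
      double mt = ma + ms;
      // distance to the next voxel face along the direction of flight
      double dby = (uy > eps) ? ((iy + 1) * voxel_cm - y) / uy
                 : (uy < -eps) ? (iy * voxel_cm - y) / uy : R_PosInf;
      double dbz = (uz > eps) ? ((iz + 1) * voxel_cm - z) / uz
                 : (uz < -eps) ? (iz * voxel_cm - z) / uz : R_PosInf;
      double db = std::min(dby, dbz);
      double s_int = (mt > 0.0) ? tau / mt : R_PosInf;
      if (s_int < db) {
        // interaction inside the current voxel
        track(iy, iz) += w * s_int;
        y += uy * s_int; z += uz * s_int;
        double dw = w * ma / mt;
        absorbed(iy, iz) += dw; tot_abs += dw; w -= dw;
        if (w <= 0.0) { alive = false; continue; }
        spin(rng, g(iy, iz), ux, uy, uz);
        tau = -std::log(runif64(rng) + 1e-300);
        if (w < roulette_weight) {
          if (runif64(rng) < roulette_survive) {
            tot_gain += w * (1.0 / roulette_survive - 1.0);
            w /= roulette_survive;
          } else {
            tot_kill += w;
            alive = false;
          }
        }
      } else {
        // cross into the neighbouring voxel
        track(iy, iz) += w * db;
        if (mt > 0.0) tau -= mt * db;
        y += uy * (db + eps); z += uz * (db + eps);
        if (z < 0.0 || z >= D) { tot_esc += w; alive = false; }
        else if (y < 0.0 || y >= W) {
          if (periodic_y) { y -= W * std::floor(y / W); }
          else { tot_esc += w; alive = false; }
        }
      }
    }
  }
  return List::create(_["absorbed"] = absorbed, _["track"] = track,
                      _["injected"] = (double)n_photons,
                      _["absorbed_total"] = tot_abs,
                      _["escaped"] = tot_esc, _["killed"] = tot_kill,
                      _["gained"] = tot_gain);
}
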