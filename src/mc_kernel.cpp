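// Weighted Monte Carlo photon transport in a layered slab (MCML-style
// hop-drop-spin), with Henyey-Greenstein scattering, Fresnel boundaries,
// Russian roulette, a cylindrical (r,z) fluence grid, a radial diffuse-
// reflectance histogram, and per-photon trajectory records (max depth,
// per-layer partial path) scored at circular surface detectors.
//
// Units: lengths in mm internally; the R wrapper converts to cm where the
// user-facing contract asks for cm.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// --- seedable counter-free RNG: xoshiro256+, seeded via splitmix64 -------
struct Xoshiro256p {
  uint64_t s[4];
  explicit Xoshiro256p(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct Layer {
  double z_top, z_bot;   // mm; z_bot = +inf for the semi-infinite last layer
  double mua, mus, mut, g, n;
};

// unpolarized Fresnel reflectance for |cos(theta_i)| = ci crossing ni -> nt
inline double fresnel(double ni, double nt, double ci) {
  if (ni == nt) return 0.0;
  if (ci > 0.999999) {
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double si = std::sqrt(1.0 - ci * ci);
  double st = ni / nt * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericMatrix layer_props,    // rows: z_top, z_bot, mua, mus, g, n (per layer)
            double n_ambient,
            NumericVector det_sep_mm,     // detector center distances from source
            double det_radius_mm,
            double n_photons,
            double seed,
            double roulette_threshold,
            double roulette_survive,
            int fluence_nr, int fluence_nz, double fluence_dr, double fluence_dz,
            int refl_nbins, double refl_dr) {
  const int nl = layer_props.nrow();
  std::vector<Layer> lay(nl);
  for (int i = 0; i < nl; ++i) {
    lay[i].z_top = layer_props(i, 0);
    lay[i].z_bot = layer_props(i, 1);
    lay[i].mua   = layer_props(i, 2);
    lay[i].mus   = layer_props(i, 3);
    lay[i].g     = layer_props(i, 4);
    lay[i].n     = layer_props(i, 5);
    lay[i].mut   = lay[i].mua + lay[i].mus;
  }
  const int nd = det_sep_mm.size();
  const double a2 = det_radius_mm * det_radius_mm;
  const long long np = (long long) n_photons;

  Xoshiro256p rng((uint64_t) seed);

  double w_reflected = 0.0, w_transmitted = 0.0, w_absorbed = 0.0;
  double w_specular = 0.0;

  std::vector<double> fluence((size_t) fluence_nr * fluence_nz, 0.0);
  std::vector<double> refl_hist(refl_nbins + 1, 0.0);  // last bin = overflow

  // per-detector record buffers
  std::vector< std::vector<double> > rec_w(nd), rec_r(nd), rec_zmax(nd),
    rec_total(nd);
  std::vector< std::vector<double> > rec_path(nd);  // flattened nl per record

  std::vector<double> partial(nl);

  const double spec_R = fresnel(n_ambient, lay[0].n, 1.0);

  for (long long ip = 0; ip < np; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    int il = 0;
    double zmax = 0.0, total_path = 0.0;
    std::fill(partial.begin(), partial.end(), 0.0);

    // specular reflection at launch
    w_specular += spec_R;
    w -= spec_R;

    double s_dimless = 0.0;  // remaining dimensionless step
    bool alive = true;
    while (alive) {
      if (s_dimless <= 0.0)
        s_dimless = -std::log(1.0 - rng.runif());

      const Layer &L = lay[il];
      // distance to the layer boundary along uz
      double db = 1e30;
      int towards = 0;  // -1 up, +1 down
      if (uz > 0.0) { db = (L.z_bot - z) / uz; towards = 1; }
      else if (uz < 0.0) { db = (L.z_top - z) / uz; towards = -1; }

      double s_geom = s_dimless / L.mut;
      if (db <= s_geom) {
        // hop to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        total_path += db; partial[il] += db;
        if (z > zmax) zmax = z;
        s_dimless -= db * L.mut;

        // medium on the far side
        double nt;
        bool to_ambient_top = false, to_ambient_bot = false;
        int il_next = il;
        if (towards < 0) {
          if (il == 0) { nt = n_ambient; to_ambient_top = true; }
          else { il_next = il - 1; nt = lay[il_next].n; }
        } else {
          if (il == nl - 1) { nt = n_ambient; to_ambient_bot = true; }
          else { il_next = il + 1; nt = lay[il_next].n; }
        }
        double ci = std::fabs(uz);
        double R = fresnel(L.n, nt, ci);
        if (rng.runif() < R) {
          uz = -uz;  // internal reflection
        } else {
          // refract
          double ratio = L.n / nt;
          double st2 = ratio * ratio * (1.0 - ci * ci);
          double ct = std::sqrt(std::max(0.0, 1.0 - st2));
          ux *= ratio; uy *= ratio;
          uz = (uz > 0.0 ? ct : -ct);
          if (to_ambient_top) {
            // photon escapes through the surface: diffuse reflectance
            w_reflected += w;
            double r_exit = std::sqrt(x * x + y * y);
            int ib = (int) (r_exit / refl_dr);
            if (ib >= refl_nbins) ib = refl_nbins;
            refl_hist[ib] += w;
            for (int d = 0; d < nd; ++d) {
              double dx = x - det_sep_mm[d];
              if (dx * dx + y * y <= a2) {
                rec_w[d].push_back(w);
                rec_r[d].push_back(r_exit);
                rec_zmax[d].push_back(zmax);
                rec_total[d].push_back(total_path);
                for (int k = 0; k < nl; ++k) rec_path[d].push_back(partial[k]);
              }
            }
            alive = false;
          } else if (to_ambient_bot) {
            w_transmitted += w;
            alive = false;
          } else {
            il = il_next;
          }
        }
        continue;
      }

      // full hop inside the layer
      x += ux * s_geom; y += uy * s_geom; z += uz * s_geom;
      total_path += s_geom; partial[il] += s_geom;
      if (z > zmax) zmax = z;
      s_dimless = 0.0;

      // drop
      double dw = w * L.mua / L.mut;
      w_absorbed += dw;
      w -= dw;
      {
        double r = std::sqrt(x * x + y * y);
        int ir = (int) (r / fluence_dr);
        int iz = (int) (z / fluence_dz);
        if (ir >= 0 && ir < fluence_nr && iz >= 0 && iz < fluence_nz)
          fluence[(size_t) iz * fluence_nr + ir] += dw;
      }

      // spin (Henyey-Greenstein)
      double g = L.g, cost;
      double u = rng.runif();
      if (std::fabs(g) > 1e-8) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
        cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
      } else {
        cost = 2.0 * u - 1.0;
      }
      double sint = std::sqrt(1.0 - cost * cost);
      double phi = 2.0 * M_PI * rng.runif();
      double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp; uy = sint * sinp;
        uz = (uz >= 0.0 ? cost : -cost);
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double uxn = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
        double uyn = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
        double uzn = -sint * cosp * tmp + uz * cost;
        ux = uxn; uy = uyn; uz = uzn;
      }

      // Russian roulette; renormalisation is folded into the absorbed
      // ledger so reflected + transmitted + absorbed == launched exactly
      if (w < roulette_threshold) {
        if (rng.runif() < roulette_survive) {
          double boost = w / roulette_survive - w;
          w_absorbed -= boost;
          w += boost;
        } else {
          w_absorbed += w;
          alive = false;
        }
      }
    }
    if (ip % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  // assemble detector records
  List detected(nd);
  for (int d = 0; d < nd; ++d) {
    int nrec = (int) rec_w[d].size();
    NumericMatrix m(nrec, 4 + nl);
    for (int i = 0; i < nrec; ++i) {
      m(i, 0) = rec_w[d][i];
      m(i, 1) = rec_r[d][i];
      m(i, 2) = rec_zmax[d][i];
      m(i, 3) = rec_total[d][i];
      for (int k = 0; k < nl; ++k) m(i, 4 + k) = rec_path[d][(size_t) i * nl + k];
    }
    detected[d] = m;
  }

  NumericMatrix flu(fluence_nz, fluence_nr);
  for (int iz = 0; iz < fluence_nz; ++iz)
    for (int ir = 0; ir < fluence_nr; ++ir)
      flu(iz, ir) = fluence[(size_t) iz * fluence_nr + ir];

  return List::create(
    _["total_reflected"]   = w_reflected + w_specular,
    _["specular"]          = w_specular,
    _["total_transmitted"] = w_transmitted,
    _["total_absorbed"]    = w_absorbed,
    _["detected"]          = detected,
    _["refl_hist"]         = NumericVector(refl_hist.begin(), refl_hist.end()),
    _["fluence"]           = flu);
}
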