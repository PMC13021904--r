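// Weighted-packet Monte-Carlo photon transport (MCML-style rules):
//   step = -ln(xi)/mu_t, per-interaction absorption w*mua/mut,
//   Henyey-Greenstein deflection, uniform azimuth,
//   Russian roulette below weight 1e-4 with survival chance 0.1.
// Two geometries: laterally infinite slab (Rd/Tt/A tallies) and a voxelized
// rectangular volume with a track-length fluence estimator.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double W_THRESHOLD = 1e-4;
static const double ROULETTE_SURVIVE = 0.1;

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : eng(seed), unif(0.0, 1.0) {}
  double u() { return unif(eng); }               // [0, 1)
  double step() { return -std::log(1.0 - unif(eng)); } // dimensionless path
};

// Inverse-CDF sample of cos(theta) for the Henyey-Greenstein phase function.
inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Unpolarized Fresnel reflection coefficient for incidence cosine cosi >= 0.
inline double fresnel_R(double n1, double n2, double cosi) {
  if (n1 == n2) return 0.0;
  if (cosi > 1.0) cosi = 1.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 * sini / n2;
  if (sint >= 1.0) return 1.0; // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cosine cost and azimuth phi.
inline void spin(double &ux, double &uy, double &uz, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0 ? cost : -cost);
  } else {
    double temp = std::sqrt(1.0 - uz * uz);
    double uxx = sint * (ux * uz * cosp - uy * sinp) / temp + ux * cost;
    double uyy = sint * (uy * uz * cosp + ux * sinp) / temp + uy * cost;
    double uzz = -sint * cosp * temp + uz * cost;
    double norm = std::sqrt(uxx * uxx + uyy * uyy + uzz * uzz);
    ux = uxx / norm; uy = uyy / norm; uz = uzz / norm;
  }
}

// [[Rcpp::export(name = ".mc_sample_hg")]]
NumericVector mc_sample_hg(double g, int n, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cost(g, rng.u());
  return out;
}

// [[Rcpp::export(name = ".hg_cost_from_u")]]
NumericVector hg_cost_from_u(double g, NumericVector u) {
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = hg_cost(g, u[i]);
  return out;
}

// Slab Monte Carlo. Pencil beam normally incident at z = 0 travelling +z.
// Returns c(Rd, Tt, A, Rsp): diffuse reflectance (specular excluded), total
// transmittance, absorbed fraction, specular reflection at entry.
// [[Rcpp::export(name = ".mc_slab")]]
NumericVector mc_slab(double mua, double mus, double g, double thickness,
                      double n_tissue, double n_above, double n_below,
                      double n_photons, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  const double mut = mua + mus;
  const long N = static_cast<long>(n_photons);
  const double rsp = fresnel_R(n_above, n_tissue, 1.0);

  double Rd = 0.0, Tt = 0.0, A = 0.0;

  for (long i = 0; i < N; ++i) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    double sleft = 0.0;
    bool alive = true;

    while (alive) {
      if (sleft <= 0.0) sleft = rng.step();
      double db; // distance to the slab face along the flight direction
      if (uz > 0.0) db = (thickness - z) / uz;
      else if (uz < 0.0) db = -z / uz;
      else db = INF;

      double s = (mut > 0.0) ? sleft / mut : INF;

      if (db <= s) { // boundary hit
        z += db * uz;
        sleft -= db * mut;
        bool going_down = uz > 0.0;
        double n_out = going_down ? n_below : n_above;
        double R = fresnel_R(n_tissue, n_out, std::fabs(uz));
        if (rng.u() < R) {
          uz = -uz; // internal reflection
        } else {
          if (going_down) Tt += w; else Rd += w;
          alive = false;
        }
      } else { // interaction
        z += s * uz;
        sleft = 0.0;
        double dw = w * mua / mut;
        A += dw;
        w -= dw;
        if (w <= 0.0) { alive = false; break; }
        double cost = hg_cost(g, rng.u());
        double phi = 2.0 * M_PI * rng.u();
        spin(ux, uy, uz, cost, phi);
        if (w < W_THRESHOLD) {
          if (rng.u() < ROULETTE_SURVIVE) w /= ROULETTE_SURVIVE;
          else alive = false;
        }
      }
    }
  }

  NumericVector out = NumericVector::create(
    _["Rd"] = Rd / N, _["Tt"] = Tt / N, _["A"] = A / N, _["Rsp"] = rsp);
  return out;
}

// Track-length deposition of a straight flight segment into the voxel grid.
static void deposit_segment(std::vector<double> &phi,
                            int nx, int ny, int nz, double h,
                            double x0, double y0, double z0,
                            double ux, double uy, double uz,
                            double L, double w) {
  if (L <= 0.0 || w <= 0.0) return;
  int ix = (int)std::floor(x0 / h);
  int iy = (int)std::floor(y0 / h);
  int iz = (int)std::floor(z0 / h);
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
  if (iz < 0) iz = 0; if (iz > nz - 1) iz = nz - 1;

  int sx = (ux > 0.0) - (ux < 0.0);
  int sy = (uy > 0.0) - (uy < 0.0);
  int sz = (uz > 0.0) - (uz < 0.0);

  double tMaxX = INF, tMaxY = INF, tMaxZ = INF;
  double tDX = INF, tDY = INF, tDZ = INF;
  if (sx != 0) {
    double plane = (sx > 0 ? (ix + 1) * h : ix * h);
    tMaxX = (plane - x0) / ux;
    tDX = h / std::fabs(ux);
  }
  if (sy != 0) {
    double plane = (sy > 0 ? (iy + 1) * h : iy * h);
    tMaxY = (plane - y0) / uy;
    tDY = h / std::fabs(uy);
  }
  if (sz != 0) {
    double plane = (sz > 0 ? (iz + 1) * h : iz * h);
    tMaxZ = (plane - z0) / uz;
    tDZ = h / std::fabs(uz);
  }

  double t = 0.0;
  while (t < L) {
    double tNext = std::min(std::min(tMaxX, tMaxY), std::min(tMaxZ, L));
    double dt = tNext - t;
    if (dt > 0.0) {
      size_t idx = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz);
      phi[idx] += w * dt;
    }
    if (tNext >= L) break;
    if (tMaxX <= tMaxY && tMaxX <= tMaxZ) { ix += sx; tMaxX += tDX; }
    else if (tMaxY <= tMaxZ) { iy += sy; tMaxY += tDY; }
    else { iz += sz; tMaxZ += tDZ; }
    t = tNext;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) break;
  }
}

// Voxel-volume Monte Carlo. The source is a flat-top disc beam of diameter
// beam_d centred on the z = 0 face, directed along +z. Faces are handled with
// Fresnel reflection/refraction when do_fresnel is true (escaping weight is
// tallied per face); otherwise every face is index-matched and transmits all
// incident weight. Fluence is w * pathlength / (voxel volume * N) per
// launched photon.
// [[Rcpp::export(name = ".mc_volume")]]
List mc_volume(double mua, double mus, double g,
               double n_tissue, double n_ambient,
               double Lx, double Ly, double Lz, double h,
               double beam_d, bool do_fresnel, double detector_radius,
               double n_photons, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  const double mut = mua + mus;
  const long N = static_cast<long>(n_photons);
  const int nx = (int)std::lround(Lx / h);
  const int ny = (int)std::lround(Ly / h);
  const int nz = (int)std::lround(Lz / h);
  std::vector<double> phi((size_t)nx * ny * nz, 0.0);

  const double rsp = do_fresnel ? fresnel_R(n_ambient, n_tissue, 1.0) : 0.0;
  // face order: x-, x+, y-, y+, z- (entry side), z+ (far side)
  std::vector<double> escaped(6, 0.0);
  double absorbed = 0.0, transmitted = 0.0;
  const double cx = Lx / 2.0, cy = Ly / 2.0;
  const double eps = 1e-9;

  for (long i = 0; i < N; ++i) {
    // uniform disc launch
    double r = 0.5 * beam_d * std::sqrt(rng.u());
    double a = 2.0 * M_PI * rng.u();
    double x = cx + r * std::cos(a), y = cy + r * std::sin(a), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    double sleft = 0.0;
    bool alive = true;

    while (alive) {
      if (sleft <= 0.0) sleft = rng.step();
      // distance to nearest face
      double db = INF; int face = -1;
      if (ux > 0.0) { double t = (Lx - x) / ux; if (t < db) { db = t; face = 1; } }
      else if (ux < 0.0) { double t = -x / ux; if (t < db) { db = t; face = 0; } }
      if (uy > 0.0) { double t = (Ly - y) / uy; if (t < db) { db = t; face = 3; } }
      else if (uy < 0.0) { double t = -y / uy; if (t < db) { db = t; face = 2; } }
      if (uz > 0.0) { double t = (Lz - z) / uz; if (t < db) { db = t; face = 5; } }
      else if (uz < 0.0) { double t = -z / uz; if (t < db) { db = t; face = 4; } }

      double s = (mut > 0.0) ? sleft / mut : INF;
      double travel = std::min(s, db);

      deposit_segment(phi, nx, ny, nz, h, x, y, z, ux, uy, uz, travel, w);
      x += travel * ux; y += travel * uy; z += travel * uz;

      if (db <= s) { // face event
        sleft -= db * mut;
        double cosi = (face <= 1) ? std::fabs(ux) : (face <= 3 ? std::fabs(uy) : std::fabs(uz));
        double R = do_fresnel ? fresnel_R(n_tissue, n_ambient, cosi) : 0.0;
        if (rng.u() < R) {
          if (face <= 1) ux = -ux; else if (face <= 3) uy = -uy; else uz = -uz;
          // nudge back inside to avoid sticking on the face plane
          x = std::min(std::max(x, eps), Lx - eps);
          y = std::min(std::max(y, eps), Ly - eps);
          z = std::min(std::max(z, eps), Lz - eps);
        } else {
          escaped[face] += w;
          if (face == 5) {
            double dx = x - cx, dy = y - cy;
            if (detector_radius <= 0.0 ||
                dx * dx + dy * dy <= detector_radius * detector_radius)
              transmitted += w;
          }
          alive = false;
        }
      } else { // interaction
        sleft = 0.0;
        double dw = w * mua / mut;
        absorbed += dw;
        w -= dw;
        if (w <= 0.0) { alive = false; break; }
        double cost = hg_cost(g, rng.u());
        double ph = 2.0 * M_PI * rng.u();
        spin(ux, uy, uz, cost, ph);
        if (w < W_THRESHOLD) {
          if (rng.u() < ROULETTE_SURVIVE) w /= ROULETTE_SURVIVE;
          else alive = false;
        }
      }
    }
  }

  const double vol = h * h * h;
  NumericVector phi_out((R_xlen_t)phi.size());
  for (size_t k = 0; k < phi.size(); ++k) phi_out[k] = phi[k] / (vol * N);
  phi_out.attr("dim") = IntegerVector::create(nx, ny, nz);
  NumericVector esc(6);
  for (int k = 0; k < 6; ++k) esc[k] = escaped[k] / N;
  esc.names() = CharacterVector::create("xlo", "xhi", "ylo", "yhi", "zlo", "zhi");

  return List::create(
    _["phi"] = phi_out,
    _["escaped"] = esc,
    _["absorbed"] = absorbed / N,
    _["transmitted"] = transmitted / N,
    _["Rsp"] = rsp);
}
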