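// Voxel-based Monte Carlo photon transport engine.
//
// Semantics (MCX/MCML lineage):
//   * dimensionless step s ~ Exp(1) is consumed against the per-voxel
//     scattering coefficient mu_s; absorption is handled by continuous
//     weight attenuation exp(-mu_a * l) along every traversed segment
//     (tracked in log space, so the inner loop needs no exp() calls);
//   * Henyey-Greenstein scattering with the local medium's g;
//   * unpolarized Fresnel reflection/refraction at the z = 0 air-tissue
//     surface only (internal boundaries index-matched);
//   * lateral and bottom faces terminate photons (escape is recorded);
//   * Russian roulette below a weight threshold, expectation-preserving;
//   * per-medium partial pathlengths and exit weight recorded for every
//     detected photon (disc or annular-ring detectors on the surface).
//
// The weight ledger {detected, absorbed, escaped_top, escaped_sides_bottom,
// roulette_killed} closes against the launched weight by construction;
// "absorbed" accumulates the continuous attenuation, "roulette_killed" is
// the net weight destroyed (kills minus survival boosts).
//
// Determinism: one private xoroshiro128+ stream per photon, seeded from
// (seed, photon index) via splitmix64. Identical (seed, config) gives a
// bitwise-identical result; systole/diastole runs sharing a seed share
// launch streams (coupled-seed variance reduction).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cfloat>
#include <vector>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  void seed(uint64_t base) {
    uint64_t x = base;
    s0 = sm64(x); s1 = sm64(x);
    if ((s0 | s1) == 0) s0 = 0x1ULL;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  // uniform in [0, 1)
  inline double u01() { return (next() >> 11) * 1.1102230246251565e-16; }
  // uniform in (0, 1)
  inline double u01o() {
    double u;
    do { u = u01(); } while (u <= 0.0);
    return u;
  }
};

// Henyey-Greenstein inverse-CDF sample of the deflection cosine.
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Unpolarized Fresnel reflectance, incidence cosine ci > 0, n1 -> n2.
static inline double fresnel_R(double ci, double n1, double n2) {
  if (n1 == n2) return 0.0;
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (s2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth psi.
static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double psi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double d = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    double nz = -st * cp * d + uz * ct;
    double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
  }
}

static const int MAXM = 15;

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector labels, IntegerVector dims, NumericVector voxel,
                NumericMatrix media, double n_ambient,
                double src_x, double src_y, double beam_sigma,
                NumericMatrix discs, NumericMatrix rings, double accept_cos,
                double n_photons, double seed,
                double rr_thresh, double rr_surv,
                bool record_transmission, bool fluence_on,
                double max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = voxel[0], hy = voxel[1], hz = voxel[2];
  const double Lx = nx * hx, Ly = ny * hy, Lz = nz * hz;
  const int M = media.nrow();
  if (M > MAXM) stop("too many media");
  double mua[MAXM], mus[MAXM], gg[MAXM], nn[MAXM];
  for (int m = 0; m < M; ++m) {
    mua[m] = media(m, 0); mus[m] = media(m, 1);
    gg[m] = media(m, 2); nn[m] = media(m, 3);
    if (!R_finite(mua[m]) || !R_finite(mus[m]) || mua[m] < 0 || mus[m] < 0 ||
        std::fabs(gg[m]) >= 1.0 || nn[m] < 1.0)
      stop("non-finite or out-of-range optical properties");
  }
  const int *lab = INTEGER(labels);
  const bool homog = (labels.size() == 1);
  const size_t nxny = (size_t)nx * ny;
  const int ndisc = discs.nrow(), nring = rings.nrow();
  const double log_thresh = std::log(rr_thresh);
  const double log_boost = std::log(1.0 / rr_surv);

  double led_det = 0.0, led_abs = 0.0, led_top = 0.0, led_sb = 0.0,
         led_rr = 0.0;
  std::vector<double> rec;       // rows: det, w, ltot, x, y, l_1..l_M
  const int ncol = 5 + M;
  rec.reserve(1024 * ncol);
  std::vector<double> flu;
  if (fluence_on) flu.assign((size_t)nx * ny * nz, 0.0);

  uint64_t sx = (uint64_t)(int64_t)seed;
  const uint64_t base = sm64(sx);
  const long long N = (long long)n_photons;
  Rng rng;

  for (long long i = 0; i < N; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed(base + (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL);

    // Gaussian launch on the surface, normal incidence.
    double x, y;
    if (beam_sigma > 0.0) {
      do {
        double r = beam_sigma * std::sqrt(-2.0 * std::log(rng.u01o()));
        double th = 2.0 * M_PI * rng.u01();
        x = src_x + r * std::cos(th);
        y = src_y + r * std::sin(th);
      } while (x < 0.0 || x >= Lx || y < 0.0 || y >= Ly);
    } else { x = src_x; y = src_y; }
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int ix = (int)(x / hx), iy = (int)(y / hy), iz = 0;
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    if (homog) { ix = 0; iy = 0; }
    size_t idx = (size_t)ix + (size_t)nx * iy;  // iz = 0

    int m = lab[homog ? 0 : idx];
    const double Rsp = fresnel_R(1.0, n_ambient, nn[m - 1]);
    led_top += Rsp;
    double logw = std::log1p(-Rsp);
    double boost_sum = 0.0;
    double lmed[MAXM] = {0.0};
    double ltot = 0.0;
    double s_rem = -std::log(rng.u01o());
    // cached inverse direction components (refreshed on direction change)
    double inv_ux = DBL_MAX, inv_uy = DBL_MAX, inv_uz = 1.0;
    long long steps = 0;

    for (;;) {
      if (++steps > (long long)max_steps) {  // safety guard, never biased off
        double w = std::exp(logw);
        led_rr += w;
        led_abs += (1.0 - Rsp) - w + boost_sum;
        break;
      }
      m = lab[homog ? 0 : idx];
      const int mi = m - 1;
      const double mus_m = mus[mi], mua_m = mua[mi];
      const double d_scat = (mus_m > 0.0) ? s_rem / mus_m : DBL_MAX;

      // homogeneous fast path: free flight fully inside the box
      if (homog && d_scat < DBL_MAX) {
        const double nxp = x + ux * d_scat, nyp = y + uy * d_scat,
                     nzp = z + uz * d_scat;
        if (nxp > 0.0 && nxp < Lx && nyp > 0.0 && nyp < Ly && nzp > 0.0 &&
            nzp < Lz) {
          double w0 = 0.0;
          if (fluence_on) w0 = std::exp(logw);
          x = nxp; y = nyp; z = nzp;
          logw -= mua_m * d_scat;
          lmed[mi] += d_scat; ltot += d_scat;
          if (fluence_on) flu[0] += w0 - std::exp(logw);
          if (logw < log_thresh) {
            double w = std::exp(logw);
            if (rng.u01() < rr_surv) {
              boost_sum += w * (1.0 / rr_surv - 1.0);
              led_rr -= w * (1.0 / rr_surv - 1.0);
              logw += log_boost;
            } else {
              led_rr += w;
              led_abs += (1.0 - Rsp) - w + boost_sum;
              break;
            }
          }
          double ct = hg_cos(gg[mi], rng.u01());
          double psi = 2.0 * M_PI * rng.u01();
          spin(ux, uy, uz, ct, psi);
          inv_ux = (ux != 0.0) ? 1.0 / ux : DBL_MAX;
          inv_uy = (uy != 0.0) ? 1.0 / uy : DBL_MAX;
          inv_uz = (uz != 0.0) ? 1.0 / uz : DBL_MAX;
          s_rem = -std::log(rng.u01o());
          continue;
        }
      }

      // distance to the voxel (or box) boundary along each axis
      double tx, ty, tz;
      if (homog) {
        tx = (ux > 0.0) ? (Lx - x) * inv_ux
                        : ((ux < 0.0) ? -x * inv_ux : DBL_MAX);
        ty = (uy > 0.0) ? (Ly - y) * inv_uy
                        : ((uy < 0.0) ? -y * inv_uy : DBL_MAX);
        tz = (uz > 0.0) ? (Lz - z) * inv_uz
                        : ((uz < 0.0) ? -z * inv_uz : DBL_MAX);
      } else {
        tx = (ux > 0.0) ? ((ix + 1) * hx - x) * inv_ux
                        : ((ux < 0.0) ? (ix * hx - x) * inv_ux : DBL_MAX);
        ty = (uy > 0.0) ? ((iy + 1) * hy - y) * inv_uy
                        : ((uy < 0.0) ? (iy * hy - y) * inv_uy : DBL_MAX);
        tz = (uz > 0.0) ? ((iz + 1) * hz - z) * inv_uz
                        : ((uz < 0.0) ? (iz * hz - z) * inv_uz : DBL_MAX);
      }
      if (tx < 0.0) tx = 0.0;
      if (ty < 0.0) ty = 0.0;
      if (tz < 0.0) tz = 0.0;
      int axis = 0; double t_exit = tx;
      if (ty < t_exit) { t_exit = ty; axis = 1; }
      if (tz < t_exit) { t_exit = tz; axis = 2; }

      if (d_scat <= t_exit) {
        // scattering event inside the current voxel
        double w0 = 0.0;
        if (fluence_on) w0 = std::exp(logw);
        x += ux * d_scat; y += uy * d_scat; z += uz * d_scat;
        logw -= mua_m * d_scat;
        lmed[mi] += d_scat; ltot += d_scat;
        if (fluence_on) flu[homog ? 0 : idx] += w0 - std::exp(logw);
        // Russian roulette
        if (logw < log_thresh) {
          double w = std::exp(logw);
          if (rng.u01() < rr_surv) {
            boost_sum += w * (1.0 / rr_surv - 1.0);
            led_rr -= w * (1.0 / rr_surv - 1.0);
            logw += log_boost;
          } else {
            led_rr += w;
            led_abs += (1.0 - Rsp) - w + boost_sum;
            break;
          }
        }
        double ct = hg_cos(gg[mi], rng.u01());
        double psi = 2.0 * M_PI * rng.u01();
        spin(ux, uy, uz, ct, psi);
        inv_ux = (ux != 0.0) ? 1.0 / ux : DBL_MAX;
        inv_uy = (uy != 0.0) ? 1.0 / uy : DBL_MAX;
        inv_uz = (uz != 0.0) ? 1.0 / uz : DBL_MAX;
        s_rem = -std::log(rng.u01o());
        continue;
      }

      // advance to the voxel/box boundary
      double w0 = 0.0;
      if (fluence_on) w0 = std::exp(logw);
      x += ux * t_exit; y += uy * t_exit; z += uz * t_exit;
      logw -= mua_m * t_exit;
      lmed[mi] += t_exit; ltot += t_exit;
      s_rem -= mus_m * t_exit;
      if (s_rem < 0.0) s_rem = 0.0;
      if (fluence_on) flu[homog ? 0 : idx] += w0 - std::exp(logw);

      bool out = false, bottom = false, top = false;
      if (axis == 0) {
        if (ux > 0.0) {
          x = homog ? Lx : (ix + 1) * hx;
          if (++ix >= nx) out = true; else ++idx;
        } else {
          x = homog ? 0.0 : ix * hx;
          if (--ix < 0) out = true; else --idx;
        }
      } else if (axis == 1) {
        if (uy > 0.0) {
          y = homog ? Ly : (iy + 1) * hy;
          if (++iy >= ny) out = true; else idx += nx;
        } else {
          y = homog ? 0.0 : iy * hy;
          if (--iy < 0) out = true; else idx -= nx;
        }
      } else {
        if (uz > 0.0) {
          z = homog ? Lz : (iz + 1) * hz;
          if (++iz >= nz) { out = true; bottom = true; } else idx += nxny;
        } else {
          z = homog ? 0.0 : iz * hz;
          if (--iz < 0) top = true; else idx -= nxny;
        }
      }

      if (top) {
        // air-tissue surface: unpolarized Fresnel decision
        double ci = -uz;
        double n1 = nn[mi];
        double Rf = fresnel_R(ci, n1, n_ambient);
        if (rng.u01() < Rf) {
          uz = -uz; inv_uz = -inv_uz; iz = 0; z = 0.0;
          continue;
        }
        double w = std::exp(logw);
        double s2 = (n1 / n_ambient) * (n1 / n_ambient) * (1.0 - ci * ci);
        double cos_t = std::sqrt(std::max(0.0, 1.0 - s2));
        int det = 0;
        if (cos_t >= accept_cos) {
          for (int d = 0; d < ndisc && det == 0; ++d) {
            double dx = x - discs(d, 0), dy = y - discs(d, 1);
            if (dx * dx + dy * dy <= discs(d, 2) * discs(d, 2)) det = d + 1;
          }
          if (det == 0 && nring > 0) {
            double dx = x - src_x, dy = y - src_y;
            double rho = std::sqrt(dx * dx + dy * dy);
            for (int d = 0; d < nring && det == 0; ++d)
              if (rho >= rings(d, 0) && rho < rings(d, 1)) det = ndisc + d + 1;
          }
        }
        if (det > 0) {
          led_det += w;
          rec.push_back((double)det); rec.push_back(w);
          rec.push_back(ltot); rec.push_back(x); rec.push_back(y);
          for (int k = 0; k < M; ++k) rec.push_back(lmed[k]);
        } else {
          led_top += w;
        }
        led_abs += (1.0 - Rsp) - w + boost_sum;
        break;
      }
      if (out) {
        double w = std::exp(logw);
        led_sb += w;
        led_abs += (1.0 - Rsp) - w + boost_sum;
        if (bottom && record_transmission) {
          rec.push_back(0.0); rec.push_back(w);
          rec.push_back(ltot); rec.push_back(x); rec.push_back(y);
          for (int k = 0; k < M; ++k) rec.push_back(lmed[k]);
        }
        break;
      }
    }
  }

  const size_t nr = rec.size() / ncol;
  NumericMatrix recm((int)nr, ncol);
  for (size_t r = 0; r < nr; ++r)
    for (int c = 0; c < ncol; ++c)
      recm((int)r, c) = rec[r * ncol + c];

  List out = List::create(
    _["launched"] = (double)N,
    _["ledger"] = NumericVector::create(
      _["detected"] = led_det,
      _["absorbed"] = led_abs,
      _["escaped_top"] = led_top,
      _["escaped_sides_bottom"] = led_sb,
      _["roulette_killed"] = led_rr),
    _["records"] = recm);
  if (fluence_on) {
    NumericVector fl(flu.begin(), flu.end());
    fl.attr("dim") = IntegerVector::create(nx, ny, nz);
    out["fluence"] = fl;
  }
  return out;
}

// Random sequential adsorption of non-overlapping circle centers in a
// rectangle [x0,x1] x [z0,z1], minimum center distance dmin. Deterministic
// for a fixed seed. Used for vessel placement in the skin cross-section.
// [[Rcpp::export]]
NumericMatrix rsa_centers_cpp(int n, double x0, double x1, double z0,
                              double z1, double dmin, double seed,
                              double max_attempts) {
  Rng rng;
  uint64_t sx = (uint64_t)(int64_t)seed;
  rng.seed(sm64(sx) ^ 0xA3C59AC2ULL);
  const double w = x1 - x0, h = z1 - z0;
  if (w <= 0 || h <= 0) stop("empty placement region");
  // cell grid with cell size >= dmin for O(1) neighbor checks
  const double cell = std::max(dmin, 1e-9);
  const int gx = std::max(1, (int)(w / cell)), gz = std::max(1, (int)(h / cell));
  const double cw = w / gx, ch = h / gz;
  std::vector<std::vector<int>> grid((size_t)gx * gz);
  std::vector<double> cx, cz;
  cx.reserve(n); cz.reserve(n);
  const double d2 = dmin * dmin;
  long long attempts = 0;
  while ((int)cx.size() < n) {
    if (++attempts > (long long)max_attempts)
      stop("vessel placement failed: density too high for non-overlapping "
           "placement in the given band");
    double px = x0 + rng.u01() * w, pz = z0 + rng.u01() * h;
    int gxi = std::min(gx - 1, (int)((px - x0) / cw));
    int gzi = std::min(gz - 1, (int)((pz - z0) / ch));
    bool ok = true;
    for (int a = std::max(0, gxi - 2); a <= std::min(gx - 1, gxi + 2) && ok; ++a)
      for (int b = std::max(0, gzi - 2); b <= std::min(gz - 1, gzi + 2) && ok; ++b)
        for (int id : grid[a + (size_t)gx * b]) {
          double dx = px - cx[id], dz = pz - cz[id];
          if (dx * dx + dz * dz < d2) { ok = false; break; }
        }
    if (ok) {
      grid[gxi + (size_t)gx * gzi].push_back((int)cx.size());
      cx.push_back(px); cz.push_back(pz);
    }
  }
  NumericMatrix outm(n, 2);
  for (int i = 0; i < n; ++i) { outm(i, 0) = cx[i]; outm(i, 1) = cz[i]; }
  return outm;
}
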