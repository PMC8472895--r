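// MCML-style photon-packet transport in a single homogeneous turbid slab.
//
// Physics: exponential free paths s = -ln(xi)/mu_t; fractional absorption
// deposit w * mu_a/mu_t per interaction, scored on a cylindrical (r, z)
// grid; Henyey-Greenstein direction updates; unpolarised Fresnel
// reflection/refraction at both slab faces; energy-conserving Russian
// roulette (a surviving packet keeps its weight; a terminated packet's
// residual weight is deposited in the local absorption bin, so the run's
// weight bookkeeping closes exactly — bias bounded by the threshold).
//
// RNG: mt19937_64 with an explicit seed; uniforms built from the top 53
// bits so the stream is identical on any conforming platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

namespace {

class Uniform01 {
  std::mt19937_64 eng;
public:
  explicit Uniform01(uint64_t seed) : eng(seed) {}
  // in [0, 1)
  double next() {
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  // in (0, 1], safe for log()
  double next_open0() { return 1.0 - next(); }
};

// Unpolarised Fresnel reflectance for incidence cosine ci in [0, 1].
double fresnel(double n_i, double n_t, double ci) {
  if (n_i == n_t) return 0.0;
  if (ci > 1.0) ci = 1.0;
  const double si2 = 1.0 - ci * ci;
  const double ratio = n_i / n_t;
  const double st2 = ratio * ratio * si2;     // sin^2 of transmitted angle
  if (st2 >= 1.0) return 1.0;                 // total internal reflection
  const double ct = std::sqrt(1.0 - st2);
  const double rs = (n_i * ci - n_t * ct) / (n_i * ci + n_t * ct);
  const double rp = (n_i * ct - n_t * ci) / (n_i * ct + n_t * ci);
  return 0.5 * (rs * rs + rp * rp);
}

double sample_hg(double xi, double g) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

} // namespace

// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double mu_a, double mu_s, double g,
                 double thickness, double n_slab, double n_above,
                 double n_below,
                 double n_photons_d, double dr, int nr, double dz, int nz,
                 int n_theta, int n_phi, double seed_d,
                 double w_threshold, double p_survival) {
  const double mu_t = mu_a + mu_s;
  if (mu_t <= 0.0) stop("mu_t = mu_a + mu_s must be positive");
  if (nz * dz < thickness - 1e-12)
    stop("depth grid does not cover the slab: nz * dz < thickness");
  const long long n_photons = (long long)n_photons_d;

  NumericMatrix a_rz(nr, nz);
  NumericMatrix r_ang(n_theta, n_phi);
  NumericMatrix t_ang(n_theta, n_phi);
  long double a_sum = 0.0L, r_sum = 0.0L, t_sum = 0.0L;

  // specular reflection of the normally incident beam at the top face
  const double r_sp = fresnel(n_above, n_slab, 1.0);

  Uniform01 rng((uint64_t)seed_d);
  const double d_theta = M_PI / 2.0 / n_theta;
  const double d_phi = 2.0 * M_PI / n_phi;

  for (long long ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - r_sp;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.next_open0()) / mu_t;

      // propagate, handling boundary crossings within this step
      while (s > 0.0) {
        double db = 1e30;
        if (uz > 0.0) db = (thickness - z) / uz;
        else if (uz < 0.0) db = -z / uz;
        if (db > s) {
          x += s * ux; y += s * uy; z += s * uz;
          s = 0.0;
        } else {
          x += db * ux; y += db * uy; z += db * uz;
          s -= db;
          const bool going_up = (uz < 0.0);
          const double n_out = going_up ? n_above : n_below;
          const double ci = std::fabs(uz);
          const double R = fresnel(n_slab, n_out, ci);
          if (rng.next() < R) {
            uz = -uz;                       // internal reflection
            z = going_up ? 0.0 : thickness; // clamp to the face
          } else {
            // escape: refract and score the exit direction
            const double st2 =
              (n_slab / n_out) * (n_slab / n_out) * (1.0 - ci * ci);
            const double ct = std::sqrt(std::max(0.0, 1.0 - st2));
            double theta = std::acos(std::min(1.0, ct));
            double phi = std::atan2(uy, ux);
            if (phi < 0.0) phi += 2.0 * M_PI;
            int it = (int)(theta / d_theta);
            if (it >= n_theta) it = n_theta - 1;
            int iph = (int)(phi / d_phi);
            if (iph >= n_phi) iph = n_phi - 1;
            if (going_up) { r_ang(it, iph) += w; r_sum += (long double)w; }
            else          { t_ang(it, iph) += w; t_sum += (long double)w; }
            alive = false;
            s = 0.0;
          }
        }
      }
      if (!alive) break;

      // absorption deposit at the interaction site
      const double r = std::sqrt(x * x + y * y);
      int ir = (int)(r / dr);
      if (ir >= nr) ir = nr - 1;              // overflow bin
      int iz = (int)(z / dz);
      if (iz >= nz) iz = nz - 1;
      const double dw = w * mu_a / mu_t;
      a_rz(ir, iz) += dw;
      a_sum += (long double)dw;
      w -= dw;
      if (w <= 0.0) break;   // fully absorbed (mu_s = 0 deposits all weight)

      // energy-conserving Russian roulette
      if (w < w_threshold) {
        if (rng.next() < p_survival) {
          // survivor keeps its weight (no 1/p boost; see package docs)
        } else {
          a_rz(ir, iz) += w;
          a_sum += (long double)w;
          alive = false;
          break;
        }
      }

      // Henyey-Greenstein scatter
      const double ct = sample_hg(rng.next(), g);
      const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      const double phi = 2.0 * M_PI * rng.next();
      const double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        const double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      // renormalise against floating-point drift
      const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }

  const double np = (double)n_photons;
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nr; ++i) a_rz(i, j) /= np;
  for (int j = 0; j < n_phi; ++j)
    for (int i = 0; i < n_theta; ++i) { r_ang(i, j) /= np; t_ang(i, j) /= np; }

  return List::create(
    _["a_rz"] = a_rz,
    _["r_specular"] = r_sp,
    _["r_diffuse"] = (double)(r_sum / np),
    _["t_diffuse"] = (double)(t_sum / np),
    _["a_total"] = (double)(a_sum / np),
    _["r_angular"] = r_ang,
    _["t_angular"] = t_ang,
    _["n_photons"] = np,
    _["seed"] = seed_d);
}

// [[Rcpp::export(name = ".sample_hg_cpp")]]
NumericVector sample_hg_cpp(NumericVector xi, double g) {
  NumericVector out(xi.size());
  for (R_xlen_t i = 0; i < xi.size(); ++i) out[i] = sample_hg(xi[i], g);
  return out;
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double n_i, double n_t, double ci) {
  return fresnel(n_i, n_t, ci);
}
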