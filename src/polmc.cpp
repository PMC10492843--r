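// Polarization-sensitive Monte Carlo photon transport through a single-layer
// slab. Photon packets carry a Stokes vector (I,Q,U,V) referenced to a local
// orthonormal frame (e1, e2, d); scattering events sample (theta, phi) from
// the polarization-dependent probability  m11(theta)*I + m12(theta)*
// (Q cos 2phi + U sin 2phi), rotate the Stokes vector into the scattering
// plane, apply the sphere Mueller matrix
//   [ m11 m12 0 0; m12 m11 0 0; 0 0 m33 m34; 0 0 -m34 m33 ]
// and renormalize so that I carries no energy (energy lives in the survival
// weight). Boundaries use the unpolarized average of the s/p Fresnel
// reflectances. Exiting photons are analyzed in the lab x/y frame aligned to
// the (x-polarized) illumination.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline void normalize(Vec3 &a) {
  double n = std::sqrt(dot(a, a));
  a.x /= n; a.y /= n; a.z /= n;
}

struct PhaseTable {
  std::vector<double> ang, m11, m12, m33, m34, cdf;
  double dang;
  int n;

  void build(const NumericVector &angles, const NumericVector &p11,
             const NumericVector &p12, const NumericVector &p33,
             const NumericVector &p34) {
    n = angles.size();
    ang.assign(angles.begin(), angles.end());
    m11.assign(p11.begin(), p11.end());
    m12.assign(p12.begin(), p12.end());
    m33.assign(p33.begin(), p33.end());
    m34.assign(p34.begin(), p34.end());
    dang = ang[1] - ang[0];
    // CDF of m11(theta) sin(theta) by trapezoid
    cdf.assign(n, 0.0);
    for (int i = 1; i < n; ++i) {
      double f0 = m11[i - 1] * std::sin(ang[i - 1]);
      double f1 = m11[i] * std::sin(ang[i]);
      cdf[i] = cdf[i - 1] + 0.5 * (f0 + f1) * (ang[i] - ang[i - 1]);
    }
    double tot = cdf[n - 1];
    for (int i = 0; i < n; ++i) cdf[i] /= tot;
  }

  double sample_theta(double u) const {
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid; else hi = mid;
    }
    double span = cdf[hi] - cdf[lo];
    double f = span > 0 ? (u - cdf[lo]) / span : 0.5;
    return ang[lo] + f * (ang[hi] - ang[lo]);
  }

  void interp(double theta, double &v11, double &v12, double &v33,
              double &v34) const {
    double t = theta / dang;
    int i = (int)t;
    if (i >= n - 1) i = n - 2;
    double f = t - i;
    v11 = m11[i] + f * (m11[i + 1] - m11[i]);
    v12 = m12[i] + f * (m12[i + 1] - m12[i]);
    v33 = m33[i] + f * (m33[i + 1] - m33[i]);
    v34 = m34[i] + f * (m34[i + 1] - m34[i]);
  }
};

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> dist{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  double u() { return dist(eng); }
};

// unpolarized average of s/p Fresnel power reflectances
double fresnel_unpolarized(double cos_i, double n_in, double n_out) {
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n_in / n_out * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// rotate Stokes reference frame by angle phi about the propagation direction
inline void rotate_stokes(double *S, double c2, double s2) {
  double Q = S[1], U = S[2];
  S[1] = c2 * Q + s2 * U;
  S[2] = -s2 * Q + c2 * U;
}

}  // namespace

// [[Rcpp::export]]
List simulate_slab_cpp(double mua, double mus, double thickness,
                       double n_inside, double n_outside,
                       NumericVector angles, NumericVector m11,
                       NumericVector m12, NumericVector m33,
                       NumericVector m34, int n_photons, double seed,
                       NumericVector stokes_in, bool matched_boundary,
                       bool collect_exits) {
  PhaseTable pt;
  pt.build(angles, m11, m12, m33, m34);
  Rng rng((uint64_t)seed);

  const double mut = mua + mus;
  const double albedo = mut > 0 ? mus / mut : 1.0;
  const double W_MIN = 1e-4, RR_SURVIVE = 0.1;

  double R_co = 0, R_cross = 0, T_tot = 0, A_tot = 0;
  std::vector<double> ex_depth, ex_co, ex_cross;
  std::vector<int> ex_nscat;

  for (int ip = 0; ip < n_photons; ++ip) {
    double z = 0.0, w = 1.0;
    Vec3 d = {0, 0, 1}, e1 = {1, 0, 0}, e2 = {0, 1, 0};
    double S[4] = {stokes_in[0], stokes_in[1], stokes_in[2], stokes_in[3]};
    if (S[0] != 1.0) { S[1] /= S[0]; S[2] /= S[0]; S[3] /= S[0]; S[0] = 1.0; }
    int nscat = 0;
    double maxz = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.u()) / mut;
      // propagate, handling boundary crossings with the remaining path
      while (true) {
        double z_new = z + d.z * s;
        if (z_new >= 0.0 && z_new <= thickness) { z = z_new; break; }
        double zb = d.z < 0 ? 0.0 : thickness;
        double t_to_b = (zb - z) / d.z;
        s -= t_to_b;
        z = zb;
        double cos_i = std::fabs(d.z);
        double Rf = matched_boundary ? 0.0
                                     : fresnel_unpolarized(cos_i, n_inside, n_outside);
        if (rng.u() < Rf) {
          // internal reflection: mirror through the interface plane
          d.z = -d.z;
          e1.z = -e1.z;
          e2 = cross(d, e1);
        } else {
          if (zb == 0.0) {
            // reflectance: analyze in the lab frame aligned to illumination x
            Vec3 xhat = {1, 0, 0};
            Vec3 xp = xhat + (-dot(xhat, d)) * d;
            double nxp = std::sqrt(dot(xp, xp));
            double Sl[4] = {S[0], S[1], S[2], S[3]};
            if (nxp > 1e-9) {
              xp = (1.0 / nxp) * xp;
              double ca = dot(e1, xp);
              double sa = dot(d, cross(e1, xp));
              double c2 = ca * ca - sa * sa, s2 = 2 * sa * ca;
              rotate_stokes(Sl, c2, s2);
            }
            double co_w = w * 0.5 * (Sl[0] + Sl[1]);
            double cr_w = w * 0.5 * (Sl[0] - Sl[1]);
            R_co += co_w;
            R_cross += cr_w;
            if (collect_exits) {
              ex_depth.push_back(maxz);
              ex_nscat.push_back(nscat);
              ex_co.push_back(co_w);
              ex_cross.push_back(cr_w);
            }
          } else {
            T_tot += w;
          }
          alive = false;
          break;
        }
      }
      if (!alive) break;

      // absorption via weight reduction
      A_tot += w * (1.0 - albedo);
      w *= albedo;
      if (z > maxz) maxz = z;

      // scattering event
      double theta = pt.sample_theta(rng.u());
      double v11, v12, v33, v34;
      pt.interp(theta, v11, v12, v33, v34);
      double r = v11 > 0 ? v12 / v11 : 0.0;
      double qu = std::sqrt(S[1] * S[1] + S[2] * S[2]);
      double bound = 1.0 + std::fabs(r) * qu;
      double phi = 0.0;
      bool ok = false;
      for (long it = 0; it < 1000000L; ++it) {
        phi = 2.0 * M_PI * rng.u();
        double acc = (1.0 + r * (S[1] * std::cos(2 * phi) +
                                 S[2] * std::sin(2 * phi))) / bound;
        if (rng.u() < acc) { ok = true; break; }
      }
      if (!ok) stop("numerical failure: azimuth rejection loop exceeded cap");

      double cphi = std::cos(phi), sphi = std::sin(phi);
      // rotate Stokes into the scattering plane
      rotate_stokes(S, cphi * cphi - sphi * sphi, 2 * sphi * cphi);
      // apply the sphere Mueller matrix
      double I2 = v11 * S[0] + v12 * S[1];
      double Q2 = v12 * S[0] + v11 * S[1];
      double U2 = v33 * S[2] + v34 * S[3];
      double V2 = -v34 * S[2] + v33 * S[3];
      S[0] = 1.0; S[1] = Q2 / I2; S[2] = U2 / I2; S[3] = V2 / I2;

      // rotate the local frame by phi about d, then deflect by theta in the
      // new (d, e1) scattering plane
      Vec3 e1r = cphi * e1 + sphi * e2;
      double ct = std::cos(theta), st = std::sin(theta);
      Vec3 dn = ct * d + st * e1r;
      Vec3 e1n = ct * e1r + (-st) * d;
      normalize(dn);
      normalize(e1n);
      d = dn; e1 = e1n;
      e2 = cross(d, e1);
      ++nscat;

      // Russian roulette (unbiased: killed weight is compensated by the
      // 1/RR_SURVIVE boost of survivors)
      if (w < W_MIN) {
        if (rng.u() < RR_SURVIVE) w /= RR_SURVIVE;
        else alive = false;
      }
    }
  }

  double n = (double)n_photons;
  List out = List::create(
      _["R_co"] = R_co / n, _["R_cross"] = R_cross / n,
      _["R_total"] = (R_co + R_cross) / n, _["T_total"] = T_tot / n,
      _["A_total"] = A_tot / n, _["n_photons"] = n_photons,
      _["seed"] = seed);
  if (collect_exits) {
    out["exit_max_depth"] = NumericVector(ex_depth.begin(), ex_depth.end());
    out["exit_n_scatter"] = IntegerVector(ex_nscat.begin(), ex_nscat.end());
    out["exit_co"] = NumericVector(ex_co.begin(), ex_co.end());
    out["exit_cross"] = NumericVector(ex_cross.begin(), ex_cross.end());
  }
  return out;
}

// Draw (theta, phi) scattering angles for a fixed incident Stokes vector;
// used to validate the sampling distribution against closed forms.
// [[Rcpp::export]]
NumericMatrix sample_scatter_cpp(NumericVector angles, NumericVector m11,
                                 NumericVector m12, NumericVector stokes,
                                 int n, double seed) {
  PhaseTable pt;
  NumericVector z(angles.size());
  pt.build(angles, m11, m12, z, z);
  Rng rng((uint64_t)seed);
  double q = stokes[1] / stokes[0], u = stokes[2] / stokes[0];
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double theta = pt.sample_theta(rng.u());
    double v11, v12, v33, v34;
    pt.interp(theta, v11, v12, v33, v34);
    double r = v11 > 0 ? v12 / v11 : 0.0;
    double bound = 1.0 + std::fabs(r) * std::sqrt(q * q + u * u);
    double phi = 0.0;
    for (long it = 0; it < 1000000L; ++it) {
      phi = 2.0 * M_PI * rng.u();
      double acc = (1.0 + r * (q * std::cos(2 * phi) + u * std::sin(2 * phi))) / bound;
      if (rng.u() < acc) break;
    }
    out(i, 0) = theta;
    out(i, 1) = phi;
  }
  return out;
}
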