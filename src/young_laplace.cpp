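#include <Rcpp.h>
using namespace Rcpp;

// Axisymmetric Young-Laplace interface integrators.
//
// Arc-length parameterization avoids the dz/dr singularity at steep angles.
// State: r (radial position), z (axial position), phi (interface inclination),
// V (enclosed solid-of-revolution volume).  Curvature balance:
//   dphi/ds + sin(phi)/r = kappa0 + c * z
// where c = +/- rho*g/sigma carries the hydrostatic contribution and kappa0
// is the (reduced) pressure jump at z = 0.  At the apex sin(phi)/r -> dphi/ds
// so dphi/ds = (kappa0 + c z)/2 there.

struct YLState {
  double r, z, phi, V;
};

static inline void yl_deriv(const YLState &st, double kappa0, double c,
                            double dphi_sign, double d[4]) {
  double curv = kappa0 + c * st.z;
  double sp = sin(st.phi), cp = cos(st.phi);
  double dphi;
  if (st.r < 1e-12) {
    dphi = curv / 2.0;
  } else {
    dphi = curv - sp / st.r;
  }
  d[0] = cp;                       // dr/ds
  d[1] = sp * dphi_sign;           // dz/ds (sign: +1 depth grows / rise grows)
  d[2] = dphi;                     // dphi/ds
  d[3] = M_PI * st.r * st.r * sp;  // dV/ds (volume swept, in |z|)
}

static inline YLState rk4_step(const YLState &st, double kappa0, double c,
                               double dphi_sign, double ds) {
  double k1[4], k2[4], k3[4], k4[4];
  YLState t;
  yl_deriv(st, kappa0, c, dphi_sign, k1);
  t = st;
  t.r = st.r + ds / 2 * k1[0]; t.z = st.z + ds / 2 * k1[1];
  t.phi = st.phi + ds / 2 * k1[2];
  yl_deriv(t, kappa0, c, dphi_sign, k2);
  t.r = st.r + ds / 2 * k2[0]; t.z = st.z + ds / 2 * k2[1];
  t.phi = st.phi + ds / 2 * k2[2];
  yl_deriv(t, kappa0, c, dphi_sign, k3);
  t.r = st.r + ds * k3[0]; t.z = st.z + ds * k3[1];
  t.phi = st.phi + ds * k3[2];
  yl_deriv(t, kappa0, c, dphi_sign, k4);
  YLState out;
  out.r   = st.r   + ds / 6 * (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]);
  out.z   = st.z   + ds / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]);
  out.phi = st.phi + ds / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]);
  out.V   = st.V   + ds / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3]);
  return out;
}

// Integrate a sessile-cap interface outward from the apex.
//
// b:  apex curvature (kappa_apex = 2*b); c = rho*g/sigma (z is depth below
// apex, so pressure jump grows with z).  Stopping rules:
//   stop_mode 1: phi >= stop_val                 (advancing/receding family)
//   stop_mode 2: r >= stop_val, first crossing   (pinned, theta <= 90 deg)
//   stop_mode 3: r <= stop_val while phi > pi/2  (pinned, theta  > 90 deg)
// Returns profile arrays (r, depth z, phi) and the enclosed volume.
// [[Rcpp::export]]
List yl_cap_integrate(double b, double c, int stop_mode, double stop_val,
                      double ds_max, int max_steps) {
  YLState st; st.r = 0.0; st.z = 0.0; st.phi = 0.0; st.V = 0.0;
  std::vector<double> rs, zs, phis;
  rs.reserve(2048); zs.reserve(2048); phis.reserve(2048);
  rs.push_back(0.0); zs.push_back(0.0); phis.push_back(0.0);
  bool hit = false;
  const double dphi_max = 0.004, phi_cap = 2.96;  // ~170 deg hard stop
  for (int i = 0; i < max_steps; ++i) {
    double curv = fabs(b * 2.0 + c * st.z) + 1e-9;
    double ds = std::min(ds_max, dphi_max / curv);
    YLState nx = rk4_step(st, 2.0 * b, c, +1.0, ds);
    bool crossed = false;
    if (stop_mode == 1 && nx.phi >= stop_val) {
      // shrink last step to land on phi == stop_val
      double frac = (stop_val - st.phi) / (nx.phi - st.phi);
      nx = rk4_step(st, 2.0 * b, c, +1.0, ds * std::max(frac, 1e-12));
      crossed = true;
    } else if (stop_mode == 2 && nx.r >= stop_val) {
      double frac = (stop_val - st.r) / (nx.r - st.r);
      nx = rk4_step(st, 2.0 * b, c, +1.0, ds * std::max(frac, 1e-12));
      crossed = true;
    } else if (stop_mode == 3 && nx.phi > M_PI_2 && nx.r <= stop_val &&
               st.r > stop_val) {
      double frac = (st.r - stop_val) / (st.r - nx.r);
      nx = rk4_step(st, 2.0 * b, c, +1.0, ds * std::max(frac, 1e-12));
      crossed = true;
    }
    st = nx;
    rs.push_back(st.r); zs.push_back(st.z); phis.push_back(st.phi);
    if (crossed) { hit = true; break; }
    if (st.phi >= phi_cap || st.phi < -1e-6) break;  // no solution this b
  }
  return List::create(_["r"] = wrap(rs), _["z"] = wrap(zs),
                      _["phi"] = wrap(phis), _["volume"] = st.V,
                      _["hit"] = hit);
}

// Integrate a wall-wetted meniscus outward from the well axis.
//
// zeta is the interface height relative to the centre (zeta(0) = 0), phi the
// inclination (positive = rising outward).  A is the reduced curvature at the
// centre; c = rho*g/sigma (higher liquid -> lower pressure -> larger concave
// curvature).  Integration runs to r = r_wall with an interpolated last step.
// [[Rcpp::export]]
List yl_wall_integrate(double A, double c, double r_wall, double ds_max,
                       int max_steps) {
  YLState st; st.r = 0.0; st.z = 0.0; st.phi = 0.0; st.V = 0.0;
  std::vector<double> rs, zs, phis;
  rs.reserve(2048); zs.reserve(2048); phis.reserve(2048);
  rs.push_back(0.0); zs.push_back(0.0); phis.push_back(0.0);
  bool hit = false;
  const double dphi_max = 0.004;
  for (int i = 0; i < max_steps; ++i) {
    double curv = fabs(A + c * st.z) + 1e-9;
    double ds = std::min(ds_max, dphi_max / curv);
    YLState nx = rk4_step(st, A, c, +1.0, ds);
    if (nx.r >= r_wall) {
      double frac = (r_wall - st.r) / (nx.r - st.r);
      nx = rk4_step(st, A, c, +1.0, ds * std::max(frac, 1e-12));
      hit = true;
    }
    st = nx;
    rs.push_back(st.r); zs.push_back(st.z); phis.push_back(st.phi);
    if (hit) break;
    if (fabs(st.phi) > 1.52) break;  // inclination beyond +/- ~87 deg
  }
  return List::create(_["r"] = wrap(rs), _["z"] = wrap(zs),
                      _["phi"] = wrap(phis), _["hit"] = hit);
}
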