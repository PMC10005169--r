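#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo photon transport through infinitely wide plane-parallel slabs.
//
// Geometry: ambient medium (n = 1) above layer 1 and below the last layer.
// Photons enter at normal incidence; the specular fraction at the top surface
// is tallied as reflected. Propagation uses the classic dimensionless-step
// bookkeeping: a sampled optical depth -log(U) is consumed across boundary
// crossings, so layers with different mu_t are handled without bias. Weight
// is deposited at each interaction (mu_a / mu_t), directions are redrawn from
// the Henyey-Greenstein phase function, and boundaries apply unpolarized
// Fresnel reflection / Snell refraction. Photons below `w_threshold` play
// Russian roulette with survival probability `roulette_p` (unbiased in
// expectation). Uses the R RNG, so results are reproducible via set.seed().
//
// mua, mus: n_wavelengths x n_layers matrices (cm^-1)
// g, n_idx: anisotropy and refractive index per layer
// d: layer thicknesses (cm)
// Returns per-wavelength reflectance (specular + diffuse escape through the
// top), transmittance (escape through the bottom) and absorbed fractions.

// [[Rcpp::export]]
List mc_multilayer(NumericMatrix mua, NumericMatrix mus,
                   NumericVector g, NumericVector n_idx,
                   NumericVector d, int n_photons,
                   double w_threshold = 1e-4, double roulette_p = 0.1) {
  const int n_w = mua.nrow();
  const int n_lay = mua.ncol();
  if (mus.nrow() != n_w || mus.ncol() != n_lay)
    stop("mua and mus dimensions must match");
  if (g.size() != n_lay || n_idx.size() != n_lay || d.size() != n_lay)
    stop("layer property lengths must match the number of layers");
  if (n_photons < 1) stop("n_photons must be positive");

  NumericVector refl(n_w), trans(n_w), absb(n_w);
  std::vector<double> zb(n_lay + 1);
  zb[0] = 0.0;
  for (int l = 0; l < n_lay; ++l) {
    if (d[l] <= 0) stop("layer thickness must be positive");
    zb[l + 1] = zb[l] + d[l];
  }

  for (int iw = 0; iw < n_w; ++iw) {
    double R = 0.0, T = 0.0, A = 0.0;
    for (int ip = 0; ip < n_photons; ++ip) {
      double w = 1.0;
      int lay = 0;
      double z = 0.0;
      double ux = 0.0, uy = 0.0, uz = 1.0;
      double rsp = (1.0 - n_idx[0]) / (1.0 + n_idx[0]);
      rsp *= rsp;
      R += rsp;
      w -= rsp;
      double sleft = 0.0;  // remaining dimensionless step (optical depth)
      bool alive = true;
      while (alive) {
        const double ma = mua(iw, lay), ms = mus(iw, lay);
        const double mt = ma + ms;
        if (sleft <= 0.0) {
          double u = unif_rand();
          if (u <= 1e-300) u = 1e-300;
          sleft = -std::log(u);
        }
        const double s_geo = (mt > 0.0) ? sleft / mt : 1e30;
        double db;
        if (uz > 0.0)      db = (zb[lay + 1] - z) / uz;
        else if (uz < 0.0) db = (zb[lay] - z) / uz;
        else               db = 1e30;
        if (db <= s_geo) {
          // reach the boundary first
          z += db * uz;
          sleft -= db * mt;
          if (sleft < 0.0) sleft = 0.0;
          const bool down = uz > 0.0;
          const int next = down ? lay + 1 : lay - 1;
          const double n1 = n_idx[lay];
          const double n2 = (next < 0 || next >= n_lay) ? 1.0 : n_idx[next];
          const double ci = std::fabs(uz);
          double r_f = 0.0, ct = ci;
          if (n1 != n2) {
            const double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
            const double st = n1 / n2 * si;
            if (st >= 1.0) {
              r_f = 1.0;
            } else {
              ct = std::sqrt(1.0 - st * st);
              const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
              const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
              r_f = 0.5 * (rs * rs + rp * rp);
            }
          }
          if (unif_rand() > r_f) {
            if (next < 0)            { R += w; alive = false; }
            else if (next >= n_lay)  { T += w; alive = false; }
            else {
              const double scale = n1 / n2;
              ux *= scale;
              uy *= scale;
              uz = down ? ct : -ct;
              lay = next;
              z = down ? zb[lay] : zb[lay + 1];
            }
          } else {
            uz = -uz;
          }
        } else {
          // interaction inside the layer
          z += s_geo * uz;
          sleft = 0.0;
          const double dw = (mt > 0.0) ? w * ma / mt : 0.0;
          A += dw;
          w -= dw;
          if (w <= 0.0) { alive = false; break; }
          const double gg = g[lay];
          double cth;
          if (std::fabs(gg) < 1e-6) {
            cth = 2.0 * unif_rand() - 1.0;
          } else {
            const double tmp = (1.0 - gg * gg) /
                               (1.0 - gg + 2.0 * gg * unif_rand());
            cth = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
            if (cth > 1.0) cth = 1.0;
            if (cth < -1.0) cth = -1.0;
          }
          const double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
          const double phi = 2.0 * M_PI * unif_rand();
          const double cp = std::cos(phi), sp = std::sin(phi);
          double nux, nuy, nuz;
          if (std::fabs(uz) > 0.99999) {
            nux = sth * cp;
            nuy = sth * sp;
            nuz = (uz >= 0.0) ? cth : -cth;
          } else {
            const double den = std::sqrt(1.0 - uz * uz);
            nux = sth * (ux * uz * cp - uy * sp) / den + ux * cth;
            nuy = sth * (uy * uz * cp + ux * sp) / den + uy * cth;
            nuz = -sth * cp * den + uz * cth;
          }
          ux = nux; uy = nuy; uz = nuz;
          if (w < w_threshold) {
            if (unif_rand() < roulette_p) w /= roulette_p;
            else alive = false;
          }
        }
      }
    }
    refl[iw] = R / n_photons;
    trans[iw] = T / n_photons;
    absb[iw] = A / n_photons;
  }
  return List::create(_["reflectance"] = refl,
                      _["transmittance"] = trans,
                      _["absorbed"] = absb);
}
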