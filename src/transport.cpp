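// Photon-transport kernels: Henyey-Greenstein sampling, a voxelized
// Monte-Carlo random walk in a homogeneous slab, and dense assembly of the
// diffusion-approximation Jacobian. All randomness comes from R's RNG so
// set.seed() in R makes every run reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample cos(theta) from the Henyey-Greenstein phase function.
static inline double hg_sample(double g) {
  double u = unif_rand();
  if (g == 0.0) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - s * s) / (2.0 * g);
}

// [[Rcpp::export]]
NumericVector cpp_hg_cos(int n, double g) {
  if (g <= -1.0 || g >= 1.0) stop("|g| must be < 1");
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_sample(g);
  return out;
}

// Fresnel reflectance for unpolarized light, internal incidence.
// n_rel = n_inside / n_outside; ci = |cos(incidence angle)|.
static inline double fresnel_R(double n_rel, double ci) {
  if (n_rel == 1.0) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = n_rel * n_rel * si2;   // sin^2(transmitted) via Snell
  if (st2 >= 1.0) return 1.0;         // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Monte-Carlo fluence in a homogeneous slab, pencil beam at (sx, sy, 0)
// directed +z. Implicit capture with Russian roulette; absorbed weight is
// deposited in the voxel containing each interaction point. Fluence is
// absorbed / (mu_a * voxel_volume * n_photons), i.e. per launched photon.
// The top surface (z = 0) applies Fresnel reflection for n_rel != 1; the
// bottom (z = thickness) and lateral boundaries are escaping.
// [[Rcpp::export]]
List cpp_mc_fluence(IntegerVector dims, NumericVector voxel, double thickness,
                    double mu_s, double mu_a, double g, double n_rel,
                    double sx, double sy, int n_photons) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const double mu_t = mu_s + mu_a;
  const double albedo = mu_s / mu_t;
  const double w_min = 1e-4, p_survive = 0.1;
  RNGScope scope;
  NumericVector fluence(nx * ny * nz);
  IntegerVector hits(nx * ny * nz);  // deposition events, for error estimates
  double absorbed = 0.0, reflected = 0.0, transmitted = 0.0;

  for (int p = 0; p < n_photons; ++p) {
    double x = sx, y = sy, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    for (int step = 0; step < 100000; ++step) {
      double s = -std::log(unif_rand()) / mu_t;
      // handle top-surface crossing (possibly several reflections not
      // needed: one crossing per hop since the slab is thick vs step)
      while (uz < 0.0 && z + s * uz < 0.0) {
        double s_to_surf = -z / uz;  // uz < 0, z >= 0
        double ci = -uz;
        if (n_rel != 1.0 && unif_rand() < fresnel_R(n_rel, ci)) {
          x += s_to_surf * ux; y += s_to_surf * uy; z = 0.0;
          uz = -uz; s -= s_to_surf;
        } else {
          reflected += w; w = 0.0; break;
        }
      }
      if (w == 0.0) break;
      x += s * ux; y += s * uy; z += s * uz;
      if (z >= thickness) { transmitted += w; break; }
      if (z < 0.0) { reflected += w; break; }  // numerical guard
      // absorb
      double dw = w * (mu_a / mu_t);
      absorbed += dw;
      int ix = (int)std::floor(x / dx), iy = (int)std::floor(y / dy),
          iz = (int)std::floor(z / dz);
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        R_xlen_t vi = ix + nx * (iy + (R_xlen_t)ny * iz);
        fluence[vi] += dw;
        hits[vi] += 1;
      }
      w *= albedo;
      if (w < w_min) {
        if (unif_rand() < p_survive) w /= p_survive;
        else break;  // roulette kill (unbiased in expectation)
      }
      // scatter: Henyey-Greenstein deflection, uniform azimuth
      double ct = hg_sample(g);
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
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
  double scale = 1.0 / (mu_a * dx * dy * dz * (double)n_photons);
  for (R_xlen_t i = 0; i < fluence.size(); ++i) fluence[i] *= scale;
  fluence.attr("dim") = IntegerVector::create(nx, ny, nz);
  hits.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["fluence"] = fluence,
                      _["hits"] = hits,
                      _["absorbed"] = absorbed / n_photons,
                      _["reflected"] = reflected / n_photons,
                      _["transmitted"] = transmitted / n_photons);
}

// Semi-infinite diffusion Green's function with extrapolated boundary:
// G = [exp(-mueff r1)/r1 - exp(-mueff r2)/r2] / (4 pi D), image source
// mirrored across z = -zb. r is clamped below r_min to avoid the
// singularity when a voxel center coincides with the effective source.
static inline double green(double px, double py, double pz,
                           double qx, double qy, double qz,
                           double D, double mueff, double zb, double r_min) {
  double ddx = qx - px, ddy = qy - py;
  double rho2 = ddx * ddx + ddy * ddy;
  double r1 = std::sqrt(rho2 + (qz - pz) * (qz - pz));
  double zi = -pz - 2.0 * zb;
  double r2 = std::sqrt(rho2 + (qz - zi) * (qz - zi));
  if (r1 < r_min) r1 = r_min;
  if (r2 < r_min) r2 = r_min;
  double val = (std::exp(-mueff * r1) / r1 - std::exp(-mueff * r2) / r2);
  return val / (4.0 * M_PI * D);
}

// Dense Born Jacobian with the diffusion engine.
// sources: ns x 2 surface positions; dets: nd x 2 kept detector offsets;
// included: logical per detector (in the inversion vector or not).
// Surface launch points are represented as isotropic point sources at
// depth z0 = 1/(mu_a + mu_s'). Two matrices are filled (included /
// excluded rows kept apart so the solver never has to subset a copy):
// row r = (s-1)*nd_group + d_group; column v = ix + nx*(iy + ny*iz).
// Entry = G(src -> voxel) * G(det -> voxel) * voxel_volume.
// [[Rcpp::export]]
List cpp_diffusion_jacobian(NumericMatrix sources, NumericMatrix dets,
                            LogicalVector included,
                            NumericVector xc, NumericVector yc,
                            NumericVector zc, double D, double mueff,
                            double z0, double zb, double voxvol,
                            double r_min) {
  const int ns = sources.nrow(), nd = dets.nrow();
  const int nx = xc.size(), ny = yc.size(), nz = zc.size();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int nd_in = 0, nd_ex = 0;
  std::vector<int> group_idx(nd);
  for (int d = 0; d < nd; ++d)
    group_idx[d] = included[d] ? nd_in++ : nd_ex++;
  NumericMatrix A((R_xlen_t)ns * nd_in, n);
  NumericMatrix E((R_xlen_t)ns * nd_ex, n);
  std::vector<double> gx(n), gm(n);
  for (int s = 0; s < ns; ++s) {
    double sxp = sources(s, 0), syp = sources(s, 1);
    R_xlen_t v = 0;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix, ++v)
          gx[v] = green(sxp, syp, z0, xc[ix], yc[iy], zc[iz],
                        D, mueff, zb, r_min);
    for (int d = 0; d < nd; ++d) {
      double dxp = sxp + dets(d, 0), dyp = syp + dets(d, 1);
      R_xlen_t v2 = 0;
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
          for (int ix = 0; ix < nx; ++ix, ++v2)
            gm[v2] = green(dxp, dyp, z0, xc[ix], yc[iy], zc[iz],
                           D, mueff, zb, r_min);
      if (included[d]) {
        R_xlen_t row = (R_xlen_t)s * nd_in + group_idx[d];
        for (R_xlen_t v3 = 0; v3 < n; ++v3)
          A(row, v3) = gx[v3] * gm[v3] * voxvol;
      } else {
        R_xlen_t row = (R_xlen_t)s * nd_ex + group_idx[d];
        for (R_xlen_t v3 = 0; v3 < n; ++v3)
          E(row, v3) = gx[v3] * gm[v3] * voxvol;
      }
    }
  }
  return List::create(_["included"] = A, _["excluded"] = E);
}
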