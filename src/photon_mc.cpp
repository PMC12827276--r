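// Monte Carlo photon transport through a planar device/tissue layer stack.
//
// MCML-style variance-reduced transport: photons carry a statistical weight,
// deposit W * mu_a/mu_t at each interaction site (collision estimator of
// fluence), deflect by Henyey-Greenstein sampling, undergo Fresnel
// reflection/refraction at every refractive-index step, and terminate by
// Russian roulette.  Geometry is a stack of laterally infinite slabs normal
// to z; z increases downward and z = 0 is the cortical (tissue) surface.
// Absorbed energy is scored on a cylindrical (r, z) grid covering z >= 0.
//
// RNG is counter-based: each photon index seeds an independent splitmix64
// stream, so results are bit-reproducible and independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t sm64_next(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform in (0, 1); never returns 0 so log() is safe
static inline double runif01(uint64_t &s) {
  return ((sm64_next(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static const double W_MIN = 1e-4;   // roulette threshold
static const double P_SURV = 0.1;   // roulette survival probability

// [[Rcpp::export]]
List mc_trace_cpp(NumericVector z_bounds,   // length nl+1, increasing, mm
                  NumericVector mu_s,       // per layer, mm^-1
                  NumericVector mu_a,
                  NumericVector g_hg,
                  NumericVector n_idx,
                  NumericVector via_r,      // >=0: opaque layer with clear via of this radius; <0: normal
                  double emitter_side,      // mm, square source at z_bounds[0]
                  int emission,             // 0 = Lambertian, 1 = collimated
                  bool mirror,              // perfect mirror behind emitter footprint
                  int tissue_boundary,      // 0-based index b such that z_bounds[b] == 0 (tissue top); -1 none
                  double n_photons,
                  double seed,
                  double dr, double dz, int nr, int nz,
                  double r_kill,            // lateral kill radius, mm
                  double det_z, double det_r) {  // detector plane; det_r < 0 disables
  const int nl = mu_s.size();
  NumericMatrix A(nr, nz);              // absorbed weight per (r, z) voxel, tissue grid
  NumericMatrix E(nr, nz);              // downward weight crossing plane z = k*dz
  NumericVector S(nr);                  // first downward crossing of z = 0 (footprint)
  NumericVector absorbed(nl);           // absorbed weight per layer (complete bookkeeping)
  double esc_top = 0, esc_bottom = 0, esc_side = 0, det_w = 0;
  double roulette_net = 0;              // killed weight minus weight added to survivors
  double into_tissue = 0;               // net weight crossing the z = 0 boundary downward
  const double half = emitter_side / 2.0;
  const double r_kill2 = r_kill * r_kill;
  const bool det_on = det_r >= 0;
  const uint64_t seed64 = (uint64_t)seed;
  const long np = (long)n_photons;

  for (long ip = 0; ip < np; ip++) {
    uint64_t rs = seed64 * 0x2545F4914F6CDD1DULL + (uint64_t)ip;
    sm64_next(rs);  // decorrelate nearby keys
    // launch
    double x = (runif01(rs) - 0.5) * emitter_side;
    double y = (runif01(rs) - 0.5) * emitter_side;
    double z = z_bounds[0];
    double ux, uy, uz;
    if (emission == 1) {
      ux = 0; uy = 0; uz = 1;
    } else {
      uz = std::sqrt(runif01(rs));                  // cosine-weighted
      double st = std::sqrt(1.0 - uz * uz);
      double phi = 2.0 * M_PI * runif01(rs);
      ux = st * std::cos(phi);
      uy = st * std::sin(phi);
    }
    double W = 1.0;
    int l = 0;
    double tau = -std::log(runif01(rs));
    bool alive = true, crossed0 = false;
    long guard = 0;

    while (alive && ++guard < 10000000L) {
      double mu_t = mu_s[l] + mu_a[l];
      // distance to layer boundary along current direction
      double db;
      int b_hit;  // boundary index if hit
      if (uz > 0)      { db = (z_bounds[l + 1] - z) / uz; b_hit = l + 1; }
      else if (uz < 0) { db = (z_bounds[l] - z) / uz;     b_hit = l; }
      else             { db = R_PosInf;                   b_hit = -1; }

      bool to_boundary = (mu_t <= 0.0) || (mu_t * db < tau);
      if (to_boundary && !R_finite(db)) { esc_side += W; break; }
      double s = to_boundary ? db : tau / mu_t;

      // detector plane crossing within this move?
      if (det_on && uz > 0 && z <= det_z && z + s * uz > det_z) {
        double sc = (det_z - z) / uz;
        double xc = x + sc * ux, yc = y + sc * uy;
        if (xc * xc + yc * yc <= det_r * det_r) { det_w += W; break; }
      }

      // downward plane-crossing tally (irradiance grid, planes z = k*dz)
      if (uz > 0) {
        double znew = z + s * uz;
        if (znew > 0) {
          int p_lo = (int)std::floor(z / dz) + 1;
          if (p_lo < 1) p_lo = 1;   // plane 0 is tallied at the boundary event
          int p_hi = (int)std::floor(znew / dz);
          if (p_hi > nz - 1) p_hi = nz - 1;
          for (int p = (p_lo < 0 ? 0 : p_lo); p <= p_hi; p++) {
            double sc = (p * dz - z) / uz;
            if (sc < 0 || sc > s) continue;
            double xc = x + sc * ux, yc = y + sc * uy;
            int ir = (int)(std::sqrt(xc * xc + yc * yc) / dr);
            if (ir < nr) {
              E(ir, p) += W;
              if (p == 0 && !crossed0) { S[ir] += W; crossed0 = true; }
            } else if (p == 0) crossed0 = true;
          }
        }
      }
      x += s * ux; y += s * uy; z += s * uz;
      if (x * x + y * y > r_kill2) { esc_side += W; break; }

      if (to_boundary) {
        tau -= mu_t * db;
        if (b_hit == 0) {                       // top surface
          if (mirror && std::fabs(x) <= half && std::fabs(y) <= half) {
            uz = -uz; z = z_bounds[0];
          } else { esc_top += W; break; }
        } else if (b_hit == nl) {               // bottom: deep escape
          esc_bottom += W; break;
        } else {
          int l_next = (uz > 0) ? b_hit : b_hit - 1;
          double n1 = n_idx[l], n2 = n_idx[l_next];
          bool transmitted;
          if (n1 == n2) {
            transmitted = true;
          } else {
            double ci = std::fabs(uz);
            double ratio = n1 / n2;
            double st2 = ratio * ratio * (1.0 - ci * ci);
            if (st2 >= 1.0) {
              transmitted = false;              // total internal reflection
            } else {
              double ct = std::sqrt(1.0 - st2);
              double rs_ = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
              double rp_ = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
              double R = 0.5 * (rs_ * rs_ + rp_ * rp_);
              if (runif01(rs) < R) {
                transmitted = false;
              } else {
                transmitted = true;
                ux *= ratio; uy *= ratio;
                uz = (uz > 0 ? 1.0 : -1.0) * ct;
              }
            }
          }
          if (transmitted) {
            if (tissue_boundary >= 0 && b_hit == tissue_boundary) {
              into_tissue += (uz > 0) ? W : -W;
              if (uz > 0) {
                int ir = (int)(std::sqrt(x * x + y * y) / dr);
                if (ir < nr) {
                  E(ir, 0) += W;
                  if (!crossed0) S[ir] += W;
                }
                crossed0 = true;
              }
            }
            l = l_next;
            // opaque interposer: photons outside the clear via are absorbed
            if (via_r[l] >= 0 && x * x + y * y > via_r[l] * via_r[l]) {
              absorbed[l] += W; break;
            }
          } else {
            uz = -uz;
            z = z_bounds[b_hit];
          }
        }
      } else {
        // interaction: absorb a fraction of the weight, then scatter
        double dW = W * mu_a[l] / mu_t;
        absorbed[l] += dW;
        if (z >= 0) {
          int ir = (int)(std::sqrt(x * x + y * y) / dr);
          int iz = (int)(z / dz);
          if (ir < nr && iz < nz) A(ir, iz) += dW;
        }
        W -= dW;
        // Henyey-Greenstein deflection
        double gg = g_hg[l], ct;
        if (std::fabs(gg) < 1e-6) {
          ct = 2.0 * runif01(rs) - 1.0;
        } else {
          double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * runif01(rs));
          ct = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
          if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        }
        double st = std::sqrt(1.0 - ct * ct);
        double phi = 2.0 * M_PI * runif01(rs);
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
        // renormalise to curb drift
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
        tau = -std::log(runif01(rs));
        // Russian roulette
        if (W < W_MIN) {
          if (runif01(rs) < P_SURV) {
            roulette_net -= W * (1.0 / P_SURV - 1.0);
            W /= P_SURV;
          } else {
            roulette_net += W;
            break;
          }
        }
      }
    }
  }

  return List::create(
    _["A"] = A,
    _["E"] = E,
    _["S"] = S,
    _["absorbed"] = absorbed,
    _["escaped_top"] = esc_top / np,
    _["escaped_bottom"] = esc_bottom / np,
    _["escaped_side"] = esc_side / np,
    _["detector"] = det_w / np,
    _["roulette_net"] = roulette_net / np,
    _["into_tissue"] = into_tissue / np,
    _["n_launched"] = (double)np);
}
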