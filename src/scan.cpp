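// Exhaustive rigid-body scan of a scanning chain around a fixed chain.
//
// For every sampled rotation x grid translation the pose is clash-checked
// (any inter-chain atom pair closer than clash_distance rejects it) and each
// distance restraint is tested on the minimum anchor-anchor distance over its
// ambiguity set. Results are accumulated as a histogram over the bitmask of
// satisfied restraints, from which accessible-space counts and violated
// fractions at any consistency level follow. Optionally, for poses reaching a
// given consistency level, per-residue inter-chain contact counts are
// accumulated (interaction-fraction analysis).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct CellList {
  double cell;          // cell edge length
  double ox, oy, oz;    // origin
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  void build(const NumericMatrix &pts, double cell_, double pad) {
    cell = cell_;
    double mnx = R_PosInf, mny = R_PosInf, mnz = R_PosInf;
    double mxx = R_NegInf, mxy = R_NegInf, mxz = R_NegInf;
    for (int i = 0; i < pts.nrow(); ++i) {
      mnx = std::min(mnx, pts(i, 0)); mxx = std::max(mxx, pts(i, 0));
      mny = std::min(mny, pts(i, 1)); mxy = std::max(mxy, pts(i, 1));
      mnz = std::min(mnz, pts(i, 2)); mxz = std::max(mxz, pts(i, 2));
    }
    ox = mnx - pad; oy = mny - pad; oz = mnz - pad;
    nx = (int)std::floor((mxx + pad - ox) / cell) + 1;
    ny = (int)std::floor((mxy + pad - oy) / cell) + 1;
    nz = (int)std::floor((mxz + pad - oz) / cell) + 1;
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < pts.nrow(); ++i) {
      int cx = (int)std::floor((pts(i, 0) - ox) / cell);
      int cy = (int)std::floor((pts(i, 1) - oy) / cell);
      int cz = (int)std::floor((pts(i, 2) - oz) / cell);
      cells[(size_t)(cx * ny + cy) * nz + cz].push_back(i);
    }
  }

  // true if any point is within `dist` of (x,y,z)
  bool any_within(const NumericMatrix &pts, double x, double y, double z,
                  double dist2) const {
    int cx = (int)std::floor((x - ox) / cell);
    int cy = (int)std::floor((y - oy) / cell);
    int cz = (int)std::floor((z - oz) / cell);
    if (cx < -1 || cx > nx || cy < -1 || cy > ny || cz < -1 || cz > nz)
      return false;
    for (int dx = -1; dx <= 1; ++dx) {
      int ix = cx + dx; if (ix < 0 || ix >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = cy + dy; if (iy < 0 || iy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int iz = cz + dz; if (iz < 0 || iz >= nz) continue;
          const std::vector<int> &v = cells[(size_t)(ix * ny + iy) * nz + iz];
          for (int j : v) {
            double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y,
                   ddz = pts(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < dist2) return true;
          }
        }
      }
    }
    return false;
  }

  // collect indices of points within `dist` of (x,y,z)
  void collect_within(const NumericMatrix &pts, double x, double y, double z,
                      double dist2, std::vector<int> &out) const {
    int cx = (int)std::floor((x - ox) / cell);
    int cy = (int)std::floor((y - oy) / cell);
    int cz = (int)std::floor((z - oz) / cell);
    for (int dx = -1; dx <= 1; ++dx) {
      int ix = cx + dx; if (ix < 0 || ix >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = cy + dy; if (iy < 0 || iy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int iz = cz + dz; if (iz < 0 || iz >= nz) continue;
          const std::vector<int> &v = cells[(size_t)(ix * ny + iy) * nz + iz];
          for (int j : v) {
            double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y,
                   ddz = pts(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < dist2) out.push_back(j);
          }
        }
      }
    }
  }
};

inline int popcount32(uint32_t x) {
  int c = 0;
  while (x) { c += x & 1u; x >>= 1; }
  return c;
}

} // namespace

// [[Rcpp::export(name = ".xlscan_cpp")]]
List xlscan_cpp(NumericMatrix fixed, NumericMatrix scan,
                IntegerVector fixed_res, IntegerVector scan_res,
                NumericMatrix rotations,   // 3K x 3, stacked row blocks
                NumericVector grid_min, IntegerVector grid_dim,
                double spacing,
                IntegerVector anchor_scan,      // per restraint, 0-based
                List anchor_fixed,              // per restraint, k x 3
                NumericVector dmin, NumericVector dmax,
                double clash_distance,
                int contact_level,              // -1: no contact accumulation
                double contact_cutoff) {
  const int S = scan.nrow();
  const int K = rotations.nrow() / 3;
  const int R = anchor_scan.size();
  if (R > 20) stop("at most 20 simultaneous restraints are supported");

  // centre the scanning chain on its centroid: translations place the centroid
  double c0 = 0, c1 = 0, c2 = 0;
  for (int i = 0; i < S; ++i) { c0 += scan(i,0); c1 += scan(i,1); c2 += scan(i,2); }
  c0 /= S; c1 /= S; c2 /= S;

  CellList clash_cl, contact_cl;
  double pad = std::max(clash_distance, 1.0);
  clash_cl.build(fixed, std::max(clash_distance, 0.5), pad);
  if (contact_level >= 0)
    contact_cl.build(fixed, contact_cutoff, contact_cutoff);

  // maximum reach of any scanning atom from the centroid: translations whose
  // distance to every fixed atom exceeds reach + clash_distance can never
  // clash under any rotation and skip the per-atom clash test
  double reach = 0;
  {
    double cc0 = 0, cc1 = 0, cc2 = 0;
    for (int i = 0; i < S; ++i) { cc0 += scan(i,0); cc1 += scan(i,1); cc2 += scan(i,2); }
    cc0 /= S; cc1 /= S; cc2 /= S;
    for (int i = 0; i < S; ++i) {
      double dx = scan(i,0) - cc0, dy = scan(i,1) - cc1, dz = scan(i,2) - cc2;
      reach = std::max(reach, std::sqrt(dx*dx + dy*dy + dz*dz));
    }
  }

  const double clash2 = clash_distance * clash_distance;
  const double contact2 = contact_cutoff * contact_cutoff;

  int n_fixed_res = 0, n_scan_res = 0;
  for (int i = 0; i < fixed.nrow(); ++i)
    n_fixed_res = std::max(n_fixed_res, fixed_res[i] + 1);
  for (int i = 0; i < S; ++i)
    n_scan_res = std::max(n_scan_res, scan_res[i] + 1);

  std::vector<double> mask_counts((size_t)1 << R, 0.0);
  std::vector<double> contact_scan_res(n_scan_res, 0.0);
  std::vector<double> contact_fixed_res(n_fixed_res, 0.0);
  double qualifying_poses = 0.0;

  // flatten ambiguity sets
  std::vector<std::vector<double>> afx(R), afy(R), afz(R);
  for (int r = 0; r < R; ++r) {
    NumericMatrix m = anchor_fixed[r];
    for (int j = 0; j < m.nrow(); ++j) {
      afx[r].push_back(m(j, 0)); afy[r].push_back(m(j, 1));
      afz[r].push_back(m(j, 2));
    }
  }

  std::vector<double> rsx(S), rsy(S), rsz(S);
  std::vector<char> scan_hit(n_scan_res), fixed_hit(n_fixed_res);
  std::vector<int> nb;

  const int gx = grid_dim[0], gy = grid_dim[1], gz = grid_dim[2];

  // rotation-independent pre-classification of translations
  std::vector<char> need_clash_check((size_t)gx * gy * gz, 0);
  if (clash_distance > 0) {
    double rcut = reach + clash_distance;
    CellList coarse_cl;
    coarse_cl.build(fixed, rcut, rcut);
    size_t gi = 0;
    for (int ix = 0; ix < gx; ++ix)
      for (int iy = 0; iy < gy; ++iy)
        for (int iz = 0; iz < gz; ++iz, ++gi) {
          double tx = grid_min[0] + spacing * ix;
          double ty = grid_min[1] + spacing * iy;
          double tz = grid_min[2] + spacing * iz;
          if (coarse_cl.any_within(fixed, tx, ty, tz, rcut * rcut))
            need_clash_check[gi] = 1;
        }
  }

  for (int k = 0; k < K; ++k) {
    // rotate centred scan coordinates: p' = Rot * (p - c)
    double Rm[9];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) Rm[a * 3 + b] = rotations(3 * k + a, b);
    for (int i = 0; i < S; ++i) {
      double x = scan(i, 0) - c0, y = scan(i, 1) - c1, z = scan(i, 2) - c2;
      rsx[i] = Rm[0] * x + Rm[1] * y + Rm[2] * z;
      rsy[i] = Rm[3] * x + Rm[4] * y + Rm[5] * z;
      rsz[i] = Rm[6] * x + Rm[7] * y + Rm[8] * z;
    }

    size_t gi = 0;
    for (int ix = 0; ix < gx; ++ix) {
      double tx = grid_min[0] + spacing * ix;
      for (int iy = 0; iy < gy; ++iy) {
        double ty = grid_min[1] + spacing * iy;
        for (int iz = 0; iz < gz; ++iz, ++gi) {
          double tz = grid_min[2] + spacing * iz;

          bool clash = false;
          if (clash_distance > 0 && need_clash_check[gi]) {
            for (int i = 0; i < S; ++i) {
              if (clash_cl.any_within(fixed, rsx[i] + tx, rsy[i] + ty,
                                      rsz[i] + tz, clash2)) {
                clash = true; break;
              }
            }
          }
          if (clash) continue;

          uint32_t mask = 0;
          for (int r = 0; r < R; ++r) {
            int s = anchor_scan[r];
            double ax = rsx[s] + tx, ay = rsy[s] + ty, az = rsz[s] + tz;
            double best = R_PosInf;
            for (size_t j = 0; j < afx[r].size(); ++j) {
              double dx = ax - afx[r][j], dy = ay - afy[r][j],
                     dz = az - afz[r][j];
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
            }
            double d = std::sqrt(best);
            if (d >= dmin[r] && d <= dmax[r]) mask |= (1u << r);
          }
          mask_counts[mask] += 1.0;

          if (contact_level >= 0 && popcount32(mask) >= contact_level) {
            qualifying_poses += 1.0;
            std::fill(scan_hit.begin(), scan_hit.end(), 0);
            std::fill(fixed_hit.begin(), fixed_hit.end(), 0);
            for (int i = 0; i < S; ++i) {
              nb.clear();
              contact_cl.collect_within(fixed, rsx[i] + tx, rsy[i] + ty,
                                        rsz[i] + tz, contact2, nb);
              if (!nb.empty()) {
                scan_hit[scan_res[i]] = 1;
                for (int j : nb) fixed_hit[fixed_res[j]] = 1;
              }
            }
            for (int i = 0; i < n_scan_res; ++i)
              if (scan_hit[i]) contact_scan_res[i] += 1.0;
            for (int i = 0; i < n_fixed_res; ++i)
              if (fixed_hit[i]) contact_fixed_res[i] += 1.0;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["mask_counts"] = NumericVector(mask_counts.begin(), mask_counts.end()),
    _["qualifying_poses"] = qualifying_poses,
    _["contact_scan_res"] = NumericVector(contact_scan_res.begin(),
                                          contact_scan_res.end()),
    _["contact_fixed_res"] = NumericVector(contact_fixed_res.begin(),
                                           contact_fixed_res.end()));
}
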