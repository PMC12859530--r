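// Monte-Carlo random-walk engine for water diffusion in a periodic ensemble
// of Voronoi cells shrunk toward their centroids. Membership in the shrunk
// cell of seed i is tested without materializing polytopes: p lies in the
// shrunk cell iff the point c_i + (p - c_i)/s maps back into the Voronoi
// cell of seed i (the shrunk cell is a subset of the parent cell because
// Voronoi cells are convex and contain their centroid).
//
// Units: positions um, time ms, diffusivity um^2/ms.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  return (x >= L) ? x - L : x; // guard against floating rounding at the edge
}

// uniform binning of seeds for nearest-neighbour queries under periodic
// boundary conditions; expanding-shell search is exact.
struct SeedGrid {
  double L, h;
  int nb, n;
  std::vector<double> sx, sy, sz;
  std::vector<std::vector<int> > bins;

  SeedGrid(const NumericMatrix& seeds, double box) {
    L = box;
    n = seeds.nrow();
    sx.resize(n); sy.resize(n); sz.resize(n);
    for (int i = 0; i < n; ++i) {
      sx[i] = wrap(seeds(i, 0), L);
      sy[i] = wrap(seeds(i, 1), L);
      sz[i] = wrap(seeds(i, 2), L);
    }
    nb = std::max(1, (int)std::floor(std::cbrt((double)std::max(n, 1))));
    h = L / nb;
    bins.assign((size_t)nb * nb * nb, std::vector<int>());
    for (int i = 0; i < n; ++i)
      bins[bin_index(sx[i], sy[i], sz[i])].push_back(i);
  }

  inline int coord_bin(double x) const {
    int b = (int)(x / h);
    if (b >= nb) b = nb - 1;
    if (b < 0) b = 0;
    return b;
  }
  inline size_t bin_index(double x, double y, double z) const {
    return ((size_t)coord_bin(x) * nb + coord_bin(y)) * nb + coord_bin(z);
  }
  inline int pmod(int a) const { int r = a % nb; return r < 0 ? r + nb : r; }

  // exact nearest seed of (x,y,z); returns -1 when there are no seeds
  int nearest(double x, double y, double z, double* d2out = 0) const {
    if (n == 0) return -1;
    x = wrap(x, L); y = wrap(y, L); z = wrap(z, L);
    int bi = coord_bin(x), bj = coord_bin(y), bk = coord_bin(z);
    int best = -1;
    double best_d2 = R_PosInf;
    int rmax = nb; // full sweep fallback
    for (int r = 0; r <= rmax; ++r) {
      // once a candidate is known, shells further than best distance cannot
      // improve: min distance to shell r is (r-1)*h
      if (best >= 0 && (double)(r - 1) * h > std::sqrt(best_d2)) break;
      bool any_scanned = false;
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj)
          for (int dk = -r; dk <= r; ++dk) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
              continue;
            if (2 * r >= nb && r > 0) {
              // shells would wrap onto themselves; brute force instead
              continue;
            }
            any_scanned = true;
            const std::vector<int>& cell =
              bins[((size_t)pmod(bi + di) * nb + pmod(bj + dj)) * nb + pmod(bk + dk)];
            for (size_t q = 0; q < cell.size(); ++q) {
              int s = cell[q];
              double dx = min_image(x - sx[s], L);
              double dy = min_image(y - sy[s], L);
              double dz = min_image(z - sz[s], L);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best_d2) { best_d2 = d2; best = s; }
            }
          }
      if (!any_scanned && r > 0) {
        // grid too coarse for shell search: brute force everything
        for (int s = 0; s < n; ++s) {
          double dx = min_image(x - sx[s], L);
          double dy = min_image(y - sy[s], L);
          double dz = min_image(z - sz[s], L);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best_d2) { best_d2 = d2; best = s; }
        }
        break;
      }
    }
    if (d2out) *d2out = best_d2;
    return best;
  }
};

// index (0-based) of the shrunk cell containing p, or -1 (extracellular)
inline int shrunk_cell(const SeedGrid& g, const NumericMatrix& centroids,
                       double s, double x, double y, double z) {
  int j = g.nearest(x, y, z);
  if (j < 0) return -1;
  if (s >= 1.0) return j; // space-filling tessellation
  double cx = centroids(j, 0), cy = centroids(j, 1), cz = centroids(j, 2);
  double qx = cx + min_image(x - cx, g.L) / s;
  double qy = cy + min_image(y - cy, g.L) / s;
  double qz = cz + min_image(z - cz, g.L) / s;
  return (g.nearest(qx, qy, qz) == j) ? j : -1;
}

inline void rand_dir(double& ux, double& uy, double& uz) {
  double nx, ny, nz, nrm;
  do {
    nx = norm_rand(); ny = norm_rand(); nz = norm_rand();
    nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  } while (nrm < 1e-12);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_assign_cells(NumericMatrix pts, NumericMatrix seeds, double L) {
  SeedGrid g(seeds, L);
  int m = pts.nrow();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = g.nearest(pts(i, 0), pts(i, 1), pts(i, 2)) + 1;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_estimate_centroids(NumericMatrix seeds, double L, int n_samples) {
  SeedGrid g(seeds, L);
  int n = seeds.nrow();
  NumericMatrix cent(n, 3);
  std::vector<double> ax(n, 0), ay(n, 0), az(n, 0);
  std::vector<int> cnt(n, 0);
  for (int i = 0; i < n_samples; ++i) {
    double x = unif_rand() * L, y = unif_rand() * L, z = unif_rand() * L;
    int j = g.nearest(x, y, z);
    if (j < 0) continue;
    ax[j] += min_image(x - g.sx[j], L);
    ay[j] += min_image(y - g.sy[j], L);
    az[j] += min_image(z - g.sz[j], L);
    cnt[j]++;
  }
  for (int j = 0; j < n; ++j) {
    cent(j, 0) = g.sx[j] + (cnt[j] ? ax[j] / cnt[j] : 0.0);
    cent(j, 1) = g.sy[j] + (cnt[j] ? ay[j] / cnt[j] : 0.0);
    cent(j, 2) = g.sz[j] + (cnt[j] ? az[j] / cnt[j] : 0.0);
  }
  return cent;
}

// [[Rcpp::export]]
IntegerVector cpp_in_shrunk_cell(NumericMatrix pts, NumericMatrix seeds,
                                 NumericMatrix centroids, double s, double L) {
  SeedGrid g(seeds, L);
  int m = pts.nrow();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = shrunk_cell(g, centroids, s, pts(i, 0), pts(i, 1), pts(i, 2)) + 1;
  return out;
}

// Intracellular residence times: walkers seeded uniformly inside shrunk
// cells diffuse with D_i; each proposed step leaving the birth cell is a
// membrane encounter accepted with probability p_cross, otherwise rejected.
// [[Rcpp::export]]
List cpp_residence(NumericMatrix seeds, NumericMatrix centroids, double s,
                   double L, double D_i, double dt, double p_cross,
                   int n_walkers, double t_max) {
  SeedGrid g(seeds, L);
  double step = std::sqrt(6.0 * D_i * dt);
  NumericVector times(n_walkers);
  LogicalVector censored(n_walkers);
  int max_steps = (int)std::ceil(t_max / dt);
  for (int w = 0; w < n_walkers; ++w) {
    // rejection-sample a start point inside any shrunk cell
    double x, y, z; int cell = -1;
    for (int tries = 0; tries < 100000 && cell < 0; ++tries) {
      x = unif_rand() * L; y = unif_rand() * L; z = unif_rand() * L;
      cell = shrunk_cell(g, centroids, s, x, y, z);
    }
    if (cell < 0) stop("could not place walker inside a cell");
    bool out = false;
    int k = 0;
    for (; k < max_steps; ++k) {
      double ux, uy, uz;
      rand_dir(ux, uy, uz);
      double nx = wrap(x + step * ux, L);
      double ny = wrap(y + step * uy, L);
      double nz = wrap(z + step * uz, L);
      int nc = shrunk_cell(g, centroids, s, nx, ny, nz);
      if (nc == cell) {
        x = nx; y = ny; z = nz;
      } else {
        if (p_cross > 0 && unif_rand() < p_cross) { out = true; ++k; break; }
        // rejected: stay put this step
      }
    }
    times[w] = k * dt;
    censored[w] = !out;
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}

// Full PGSE walk. Walkers start uniformly in the box (stationary
// distribution of the two-compartment system). Per-walker output is the
// gradient-direction displacement integral
//   F = int_lobe1 u(t) dt - int_lobe2 u(t) dt   (um * ms)
// from which the phase at any b follows as phi = gammaG(b) * F with
// gammaG = sqrt(b_eff / (Delta - delta/3)) / delta.
// p_io: crossing probability for intra->extra encounters; extra->intra uses
// p_io * sqrt(D_i/D_e) to preserve the equilibrium intracellular fraction.
// [[Rcpp::export]]
List cpp_walk(NumericMatrix seeds, NumericMatrix centroids, double s, double L,
              double D_i, double D_e, double p_io, double dt,
              double delta, double Delta, int n_walkers) {
  SeedGrid g(seeds, L);
  bool has_cells = seeds.nrow() > 0 && s > 0;
  double step_i = std::sqrt(6.0 * D_i * dt);
  double step_e = std::sqrt(6.0 * D_e * dt);
  double p_oi = p_io * std::sqrt(D_i / D_e);
  if (p_oi > 1) p_oi = 1;
  double T = Delta + delta;
  int n_steps = (int)std::ceil(T / dt);

  NumericVector F(n_walkers);
  LogicalVector start_in(n_walkers), crossed(n_walkers), end_in(n_walkers);

  // overlap weight of step interval [t0,t1) with the two gradient lobes
  // (+ lobe over [0,delta), - lobe over [Delta, Delta+delta))
  for (int w = 0; w < n_walkers; ++w) {
    double x = unif_rand() * L, y = unif_rand() * L, z = unif_rand() * L;
    int cell = has_cells ? shrunk_cell(g, centroids, s, x, y, z) : -1;
    start_in[w] = cell >= 0;
    crossed[w] = false;
    double u = 0.0;   // unwrapped displacement along the gradient direction
    double Fw = 0.0;
    for (int k = 0; k < n_steps; ++k) {
      double t0 = k * dt, t1 = std::min(T, t0 + dt);
      double ux, uy, uz;
      rand_dir(ux, uy, uz);
      double stp = (cell >= 0) ? step_i : step_e;
      double nx = wrap(x + stp * ux, L);
      double ny = wrap(y + stp * uy, L);
      double nz = wrap(z + stp * uz, L);
      double du = stp * uy; // gradient along y
      bool moved = true;
      if (has_cells) {
        int nc = shrunk_cell(g, centroids, s, nx, ny, nz);
        if (nc != cell) {
          double p = (cell >= 0) ? p_io : p_oi;
          if (unif_rand() < p) {
            crossed[w] = true;
            cell = nc;
          } else {
            moved = false;
          }
        }
      }
      double u_new = moved ? u + du : u;
      if (moved) { x = nx; y = ny; z = nz; }
      // trapezoid within the step, split by lobe overlap
      double w1a = std::max(0.0, std::min(t1, delta) - t0);
      double w2a = std::max(0.0, std::min(t1, Delta + delta) - std::max(t0, Delta));
      double u_mid = 0.5 * (u + u_new);
      Fw += u_mid * (w1a - w2a);
      u = u_new;
    }
    F[w] = Fw;
    end_in[w] = cell >= 0;
  }
  return List::create(_["F"] = F, _["start_inside"] = start_in,
                      _["crossed"] = crossed, _["end_inside"] = end_in);
}
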