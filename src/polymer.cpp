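#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Overdamped bead-spring sampler (kT = 1, friction = 1, lengths in monomer
// diameters): harmonic backbone springs, harmonic extruder bonds with a
// force cap below the backbone scale (so freshly switched long-range bonds
// contract smoothly instead of tearing the chain), and a soft linear-ramp
// excluded-volume repulsion. A per-monomer cap on the deterministic
// displacement per step keeps dense conformations stable. Euler-Maruyama
// update x += F dt + sqrt(2 dt) eta, using R's RNG.

// Neighbor search over a uniform grid. Dense cell array when the bounding
// box is compact; sorted-cell-key fallback for sparse, extended chains.
struct NeighborGrid {
  double cell, ox, oy, oz;
  int64_t nx, ny, nz;
  bool dense;
  std::vector<int> head, nxt;                  // dense mode
  std::vector<std::pair<int64_t, int>> keys;   // sparse mode, sorted
  inline int64_t key(int64_t cx, int64_t cy, int64_t cz) const {
    return (cz * ny + cy) * nx + cx;
  }
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cutoff) {
    const int N = x.size();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < N; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    if (!std::isfinite(xmin) || !std::isfinite(xmax) ||
        !std::isfinite(ymin) || !std::isfinite(ymax) ||
        !std::isfinite(zmin) || !std::isfinite(zmax))
      stop("integration-instability error: coordinates diverged; use a smaller dt_3d");
    cell = cutoff; ox = xmin; oy = ymin; oz = zmin;
    nx = (int64_t)((xmax - xmin) / cell) + 1;
    ny = (int64_t)((ymax - ymin) / cell) + 1;
    nz = (int64_t)((zmax - zmin) / cell) + 1;
    const double ncell = (double)nx * ny * nz;
    dense = ncell <= 4e6;
    if (dense) {
      head.assign((size_t)(nx * ny * nz), -1);
      nxt.assign(N, -1);
      for (int i = 0; i < N; ++i) {
        const int64_t c = key((int64_t)((x[i] - ox) / cell),
                              (int64_t)((y[i] - oy) / cell),
                              (int64_t)((z[i] - oz) / cell));
        nxt[i] = head[c]; head[c] = i;
      }
    } else {
      keys.resize(N);
      for (int i = 0; i < N; ++i)
        keys[i] = {key((int64_t)((x[i] - ox) / cell),
                       (int64_t)((y[i] - oy) / cell),
                       (int64_t)((z[i] - oz) / cell)), i};
      std::sort(keys.begin(), keys.end());
    }
  }
  // visit all particles in the 27-cell neighborhood of particle i
  template <typename F>
  void neighbors(int i, const std::vector<double>& x,
                 const std::vector<double>& y, const std::vector<double>& z,
                 F&& fn) const {
    const int64_t cx = (int64_t)((x[i] - ox) / cell),
                  cy = (int64_t)((y[i] - oy) / cell),
                  cz = (int64_t)((z[i] - oz) / cell);
    for (int64_t dz = -1; dz <= 1; ++dz)
      for (int64_t dy = -1; dy <= 1; ++dy)
        for (int64_t dx = -1; dx <= 1; ++dx) {
          const int64_t ax = cx + dx, ay = cy + dy, az = cz + dz;
          if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
            continue;
          const int64_t k = key(ax, ay, az);
          if (dense) {
            for (int j = head[k]; j >= 0; j = nxt[j]) fn(j);
          } else {
            auto lo = std::lower_bound(
                keys.begin(), keys.end(), std::make_pair(k, -1));
            for (; lo != keys.end() && lo->first == k; ++lo) fn(lo->second);
          }
        }
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_advance_polymer(NumericMatrix coords, IntegerMatrix bonds,
                                  double k_backbone, double r0_backbone,
                                  double k_bond, double r0_bond,
                                  double ev_strength, double ev_radius,
                                  double dt, int n_steps, double f_max,
                                  double disp_max, double conf_radius,
                                  double conf_k) {
  const int N = coords.nrow();
  const int NB = bonds.nrow();
  std::vector<double> x(N), y(N), z(N), fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  NeighborGrid grid;
  const double noise = std::sqrt(2.0 * dt);

  // `cap` bounds the spring force: extruder bonds are capped below what the
  // backbone can resist, so long-range bonds contract at constant speed
  auto spring = [&](int i, int j, double k, double r0, double cap) {
    const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) return;
    double f = k * (r - r0);                 // pull i toward j when stretched
    if (f > cap) f = cap;
    if (f < -cap) f = -cap;
    const double s = f / r;
    fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
    fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
  };

  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int i = 0; i + 1 < N; ++i)
      spring(i, i + 1, k_backbone, r0_backbone, 1e12);
    for (int b = 0; b < NB; ++b)
      spring(bonds(b, 0), bonds(b, 1), k_bond, r0_bond, f_max);

    if (ev_strength > 0.0) {
      grid.build(x, y, z, ev_radius);
      const double r2c = ev_radius * ev_radius;
      for (int i = 0; i < N; ++i) {
        grid.neighbors(i, x, y, z, [&](int j) {
          if (j <= i) return;
          const double ddx = x[j] - x[i], ddy = y[j] - y[i],
                       ddz = z[j] - z[i];
          const double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (r2 >= r2c || r2 < 1e-18) return;
          const double r = std::sqrt(r2);
          const double f = ev_strength * (1.0 - r / ev_radius) / ev_radius;
          const double s = f / r;            // push apart
          fx[i] -= s * ddx; fy[i] -= s * ddy; fz[i] -= s * ddz;
          fx[j] += s * ddx; fy[j] += s * ddy; fz[j] += s * ddz;
        });
      }
    }
    if (conf_radius > 0.0) {
      // harmonic wall of a sphere centered at the origin
      for (int i = 0; i < N; ++i) {
        const double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > conf_radius && r > 1e-12) {
          const double s = -conf_k * (r - conf_radius) / r;
          fx[i] += s * x[i]; fy[i] += s * y[i]; fz[i] += s * z[i];
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      // cap the deterministic displacement so dense regions stay stable
      double dx = dt * fx[i], dy = dt * fy[i], dz = dt * fz[i];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > disp_max) {
        const double s = disp_max / d;
        dx *= s; dy *= s; dz *= s;
      }
      x[i] += dx + noise * norm_rand();
      y[i] += dy + noise * norm_rand();
      z[i] += dz + noise * norm_rand();
    }
  }

  for (int i = 0; i + 1 < N; ++i) {
    const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                 dz = z[i + 1] - z[i];
    if (std::sqrt(dx * dx + dy * dy + dz * dz) > 2.0 * r0_backbone + 2.0)
      stop("integration-instability error: chain break detected; use a smaller dt_3d");
  }

  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return out;
}

// All unordered monomer pairs with |i-j| >= min_sep whose Euclidean distance
// is below `radius`. Returns 0-based index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_capture_contacts(NumericMatrix coords, double radius,
                                   int min_sep) {
  const int N = coords.nrow();
  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  NeighborGrid grid;
  grid.build(x, y, z, radius);
  std::vector<int> pi, pj;
  const double r2c = radius * radius;
  for (int i = 0; i < N; ++i) {
    grid.neighbors(i, x, y, z, [&](int j) {
      if (j <= i || j - i < min_sep) return;
      const double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
      if (ddx * ddx + ddy * ddy + ddz * ddz < r2c) {
        pi.push_back(i); pj.push_back(j);
      }
    });
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k]; out(k, 1) = pj[k];
  }
  return out;
}
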