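#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-timestep 1D lattice loop-extrusion simulation with dynamic barriers.
//
// Update order per timestep (documented contract):
//   (1) barrier flips, (2) extruder unbind/instant reload, (3) leg steps in
//   random order over all legs.
// Blocking rule: a bound barrier whose orientation matches a leg's travel
// direction refuses the step *past* its site, so a blocked leg comes to rest
// ON the barrier site. Replica boundaries are impassable. All randomness is
// drawn from R's RNG, so set.seed() gives bit-identical runs.

static inline bool coin(double p) { return p > 0.0 && unif_rand() < p; }

// [[Rcpp::export]]
List cpp_run_lattice(int n_sites, int n_replicas, int extruder_separation,
                     double tau_E, double p_step, double dt,
                     IntegerVector barrier_site,   // global 0-based sites
                     IntegerVector barrier_dir,    // +1 blocks rightward legs, -1 leftward
                     NumericVector tau_b, NumericVector tau_u,
                     LogicalVector bound_init,
                     int n_updates, int burn_updates, int stride,
                     int max_load_tries) {
  const int total = n_sites * n_replicas;
  const int per_rep = n_sites / extruder_separation;
  const int E = per_rep * n_replicas;
  const int B = barrier_site.size();

  std::vector<char> occ(total, 0);
  std::vector<int> bar_at(total, -1);
  std::vector<char> bound(B);
  std::vector<double> p_unbind(B), p_bind(B);
  for (int b = 0; b < B; ++b) {
    if (barrier_site[b] < 0 || barrier_site[b] >= total)
      stop("barrier site out of range");
    bar_at[barrier_site[b]] = b;
    bound[b] = bound_init[b] ? 1 : 0;
    p_unbind[b] = std::isinf(tau_b[b]) ? 0.0 : dt / tau_b[b];
    p_bind[b]   = (tau_u[b] == 0.0) ? 1.0 :
                  (std::isinf(tau_u[b]) ? 0.0 : dt / tau_u[b]);
    if (p_unbind[b] > 1.0 || p_bind[b] > 1.0)
      stop("invalid timestep: per-update flip probability dt/tau exceeds 1");
  }
  const double p_die = std::isinf(tau_E) ? 0.0 : dt / tau_E;
  if (p_die > 1.0) stop("invalid timestep: dt/tau_E exceeds 1");
  if (p_step > 1.0) stop("invalid timestep: leg step probability exceeds 1");

  std::vector<int> left(E), right(E), rep_of(E);

  // uniform reload over unoccupied adjacent site pairs within a replica
  auto load = [&](int e, int rep) {
    const int lo = rep * n_sites;
    for (int t = 0; t < max_load_tries; ++t) {
      int s = lo + (int)std::floor(unif_rand() * (n_sites - 1));
      if (s >= lo + n_sites - 1) s = lo + n_sites - 2;
      if (!occ[s] && !occ[s + 1]) {
        left[e] = s; right[e] = s + 1;
        occ[s] = occ[s + 1] = 1;
        return;
      }
    }
    stop("simulation-density error: no free loading site after %d tries",
         max_load_tries);
  };

  for (int e = 0; e < E; ++e) {
    rep_of[e] = e / per_rep;
    load(e, rep_of[e]);
  }

  const int n_frames = (n_updates - burn_updates) / stride;
  if (n_frames < 1) stop("no frames to sample");
  NumericVector times(n_frames);
  IntegerMatrix out_left(n_frames, E), out_right(n_frames, E);
  LogicalMatrix out_bound(n_frames, B);

  std::vector<int> legs(2 * E);
  for (int i = 0; i < 2 * E; ++i) legs[i] = i;

  int frame = 0;
  for (int u = 1; u <= n_updates; ++u) {
    // (1) barrier flips
    for (int b = 0; b < B; ++b) {
      if (bound[b]) { if (coin(p_unbind[b])) bound[b] = 0; }
      else          { if (coin(p_bind[b]))   bound[b] = 1; }
    }
    // (2) extruder turnover with instant reload
    if (p_die > 0.0) {
      for (int e = 0; e < E; ++e) {
        if (coin(p_die)) {
          occ[left[e]] = 0; occ[right[e]] = 0;
          load(e, rep_of[e]);
        }
      }
    }
    // (3) leg steps, random order (Fisher-Yates)
    for (int i = 2 * E - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(legs[i], legs[j]);
    }
    for (int i = 0; i < 2 * E; ++i) {
      const int e = legs[i] / 2;
      const bool is_right = legs[i] % 2;
      if (!coin(p_step)) continue;
      if (is_right) {
        const int p = right[e], q = p + 1;
        if (q >= (rep_of[e] + 1) * n_sites) continue;          // replica edge
        if (occ[q]) continue;                                  // leg collision
        const int b = bar_at[p];
        if (b >= 0 && bound[b] && barrier_dir[b] == 1) continue; // blocked
        occ[p] = 0; occ[q] = 1; right[e] = q;
      } else {
        const int p = left[e], q = p - 1;
        if (q < rep_of[e] * n_sites) continue;
        if (occ[q]) continue;
        const int b = bar_at[p];
        if (b >= 0 && bound[b] && barrier_dir[b] == -1) continue;
        occ[p] = 0; occ[q] = 1; left[e] = q;
      }
    }
    if (u > burn_updates && (u - burn_updates) % stride == 0 && frame < n_frames) {
      times[frame] = u * dt;
      for (int e = 0; e < E; ++e) {
        out_left(frame, e) = left[e];
        out_right(frame, e) = right[e];
      }
      for (int b = 0; b < B; ++b) out_bound(frame, b) = bound[b] != 0;
      ++frame;
    }
  }

  return List::create(_["times"] = times, _["left"] = out_left,
                      _["right"] = out_right, _["bound"] = out_bound,
                      _["n_extruders"] = E);
}

// Telegraph-only integrator used for occupancy checks: returns per-barrier
// bound-time fraction and flip count over n_updates.
// [[Rcpp::export]]
List cpp_run_telegraph(NumericVector tau_b, NumericVector tau_u,
                       LogicalVector bound_init, double dt, int n_updates) {
  const int B = tau_b.size();
  std::vector<char> bound(B);
  NumericVector frac(B);
  IntegerVector flips(B);
  for (int b = 0; b < B; ++b) {
    bound[b] = bound_init[b] ? 1 : 0;
    const double pu = std::isinf(tau_b[b]) ? 0.0 : dt / tau_b[b];
    const double pb = (tau_u[b] == 0.0) ? 1.0 : dt / tau_u[b];
    if (pu > 1.0 || pb > 1.0)
      stop("invalid timestep: per-update flip probability dt/tau exceeds 1");
  }
  for (int u = 0; u < n_updates; ++u) {
    for (int b = 0; b < B; ++b) {
      const double pu = std::isinf(tau_b[b]) ? 0.0 : dt / tau_b[b];
      const double pb = (tau_u[b] == 0.0) ? 1.0 : dt / tau_u[b];
      if (bound[b]) { if (coin(pu)) { bound[b] = 0; ++flips[b]; } }
      else          { if (coin(pb)) { bound[b] = 1; ++flips[b]; } }
      if (bound[b]) frac[b] += 1.0;
    }
  }
  for (int b = 0; b < B; ++b) frac[b] /= n_updates;
  return List::create(_["bound_fraction"] = frac, _["flips"] = flips);
}
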