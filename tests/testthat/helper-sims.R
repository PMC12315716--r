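# shared scaled-simulation helpers for the observable-level tests

# one-replica 2.5-Mb reference lattice with shared barrier kinetics
scaled_trace <- function(tau_b, tau_u, tau_E, n_frames, sample_every,
                         seed, layout_seed = 42, static = FALSE) {
  lay <- random_layout(2.5e6, 32, tau_b, tau_u, seed = layout_seed)
  cfg <- lattice_config(n_sites = 10000, n_replicas = 1, tau_E = tau_E,
                        seed = seed)
  tr <- run_lattice(cfg, lay, duration = 3 * tau_E + n_frames * sample_every,
                    sample_every = sample_every, static = static)
  list(trace = tr, layout = lay)
}

# FRiP from a scaled run plus a block-wise standard error (blocks across
# time absorb the autocorrelation of leg positions)
frip_with_se <- function(tr, lay, n_blocks = 8) {
  sites <- barrier_sites(lay)
  n_frames <- length(tr$trace$times)
  block <- floor(n_frames / n_blocks)
  vals <- vapply(seq_len(n_blocks), function(b) {
    rows <- ((b - 1) * block + 1):(b * block)
    sub <- tr$trace
    sub$times <- sub$times[rows]
    sub$left <- sub$left[rows, , drop = FALSE]
    sub$right <- sub$right[rows, , drop = FALSE]
    frip(accumulate_track(sub), sites)
  }, numeric(1))
  list(frip = frip(accumulate_track(tr$trace), sites),
       se = stats::sd(vals) / sqrt(n_blocks))
}

# coupled lattice -> polymer -> map scores at the scaled size
scaled_map_scores <- function(tau_b, tau_E, occ = 0.7, n_frames = 1500,
                              sample_every = 10, steps_per_frame = 150,
                              seed = 61, keep = 0) {
  run <- scaled_trace(tau_b, tau_b * (1 - occ) / occ, tau_E,
                      n_frames, sample_every, seed)
  ens <- run_polymer(run$trace,
                     polymer_config(steps_per_frame = steps_per_frame,
                                    seed = seed + 1),
                     keep_conformations = keep)
  map <- aggregate_map(ens, 10000)
  list(
    frip = frip(accumulate_track(run$trace), barrier_sites(run$layout)),
    insulation = insulation_score(map, barrier_bins(run$layout, 10000)),
    dot = mean_dot_score(dot_profile(map,
                                     convergent_pairs(run$layout, 10000))),
    ensemble = ens
  )
}
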