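#' Accumulate an in silico ChIP-seq track from a lattice trace
#'
#' Tallies extruder leg visits per lattice site across all sampled frames.
#' Since barrier layouts are identical across replicas, counts are collapsed
#' onto within-replica site positions (the per-site average over replicas up
#' to the retained denominator), mirroring how simulated ChIP-seq tracks are
#' averaged over replicas.
#'
#' @param trace A `lattice_trace` from [run_lattice()].
#' @return An `occupancy_track` tibble with 0-based `site` and `count`,
#'   carrying `n_frames`, `n_replicas`, `n_extruders`, `n_sites` and
#'   `site_bp` as attributes. `sum(count)` equals
#'   `2 * n_extruders * n_frames`.
#' @export
accumulate_track <- function(trace) {
  stopifnot(inherits(trace, "lattice_trace"))
  if (length(trace$times) == 0) abort("empty trace")
  n_sites <- trace$config$n_sites
  legs <- c(trace$left, trace$right) %% n_sites
  counts <- tabulate(legs + 1L, nbins = n_sites)
  out <- tibble::tibble(site = seq_len(n_sites) - 1L, count = counts)
  structure(out, class = c("occupancy_track", class(out)),
            n_frames = length(trace$times),
            n_replicas = trace$config$n_replicas,
            n_extruders = trace$n_extruders,
            n_sites = n_sites, site_bp = trace$config$site_bp)
}

#' Fraction of extruder legs at barrier positions (simulated FRiP)
#'
#' The in silico analogue of the fraction of cohesin ChIP-seq reads in CTCF
#' peaks: the share of recorded leg observations that sit exactly on barrier
#' lattice sites (a "read at a peak" is a leg on the barrier site itself,
#' consistent with blocked legs resting on the barrier site). A flanking
#' window can be added for sensitivity analyses.
#'
#' @param track An `occupancy_track` from [accumulate_track()].
#' @param barrier_sites Integer vector of 0-based within-replica lattice
#'   sites (see [barrier_sites()]).
#' @param window Number of flanking sites on each side also counted as "in
#'   peak" (default 0, the parameter-free definition).
#' @return FRiP in `[0, 1]`.
#' @export
frip <- function(track, barrier_sites, window = 0) {
  total <- sum(track$count)
  if (total == 0) abort("empty track")
  if (length(barrier_sites) == 0) return(0)
  n_sites <- attr(track, "n_sites")
  if (any(barrier_sites < 0 | barrier_sites >= n_sites))
    abort("barrier_sites outside the lattice")
  sites <- unique(as.vector(outer(barrier_sites, -window:window, `+`)))
  sites <- sites[sites >= 0 & sites < n_sites]
  sum(track$count[track$site %in% sites]) / total
}
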