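#' Polymer sampler configuration
#'
#' The 3D side of the model is a self-contained overdamped bead-spring
#' sampler in reduced units (kT = 1, friction = 1, lengths in monomer
#' diameters, one monomer = 2.5 kb of a 50-nm fiber). Backbone and extruder
#' bonds are harmonic with a force cap so a freshly switched long-range
#' extruder bond contracts smoothly instead of destabilising the integrator;
#' excluded volume is a soft linear-ramp repulsion that permits strand
#' passage, as appropriate for a coarse chromatin fiber. Its fidelity target
#' is ensemble contact statistics, not calibrated dynamics.
#'
#' @param monomer_bp Base pairs per monomer; must be a multiple of the
#'   lattice `site_bp`.
#' @param bond_length Backbone rest length (monomer diameters).
#' @param k_backbone,k_bond Spring constants (kT per diameter^2) for backbone
#'   and extruder bonds.
#' @param bond_rest Extruder-bond rest length.
#' @param excluded_volume_strength Soft repulsion energy scale (kT); 0
#'   disables excluded volume (ideal chain).
#' @param excluded_volume_radius Repulsion range (diameters).
#' @param dt_3d Integrator timestep (reduced time).
#' @param steps_per_frame Relaxation steps after each lattice frame's bond
#'   switch, before the frame is harvested.
#' @param init_steps Extra relaxation steps before the first frame.
#' @param init_persistence Persistence (monomers) of the initial
#'   conformation's step directions; positive values start from an
#'   extended, decondensed fiber.
#' @param capture_radius Contact capture distance (diameters).
#' @param f_max Extruder-bond force cap (kT per diameter); kept below the
#'   backbone spring scale so long-range bonds contract without tearing the
#'   chain.
#' @param disp_max Cap on the deterministic displacement per monomer per
#'   step (diameters); keeps dense conformations numerically stable.
#' @param confinement_radius Radius of a harmonic-wall spherical confinement
#'   centered at the origin (diameters); 0 disables it. Confinement at a
#'   nucleus-like density is how whole-chromosome morphology comparisons are
#'   set up, since it fixes the volume an uncondensed fiber explores.
#' @param confinement_k Wall spring constant (kT per diameter^2).
#' @param seed RNG seed.
#' @return A `polymer_config` object.
#' @export
polymer_config <- function(monomer_bp = 2500, bond_length = 1,
                           k_backbone = 100, k_bond = 100, bond_rest = 0.5,
                           excluded_volume_strength = 3,
                           excluded_volume_radius = 1,
                           dt_3d = 0.005, steps_per_frame = 200,
                           init_steps = 2000, init_persistence = 0,
                           capture_radius = 2,
                           f_max = 20, disp_max = 0.2,
                           confinement_radius = 0, confinement_k = 5,
                           seed = 1L) {
  if (capture_radius <= 0) abort("capture_radius must be > 0")
  structure(list(monomer_bp = monomer_bp, bond_length = bond_length,
                 k_backbone = k_backbone, k_bond = k_bond,
                 bond_rest = bond_rest,
                 excluded_volume_strength = excluded_volume_strength,
                 excluded_volume_radius = excluded_volume_radius,
                 dt_3d = dt_3d, steps_per_frame = as.integer(steps_per_frame),
                 init_steps = as.integer(init_steps),
                 init_persistence = init_persistence,
                 capture_radius = capture_radius, f_max = f_max,
                 disp_max = disp_max,
                 confinement_radius = confinement_radius,
                 confinement_k = confinement_k,
                 seed = as.integer(seed)),
            class = "polymer_config")
}

#' Coarse-grain extruder legs to monomer bonds
#'
#' Each extruder contributes one harmonic bond between the monomers holding
#' its two legs, `floor(leg * site_bp / monomer_bp)`; extruders whose legs
#' fall in the same monomer contribute no bond.
#'
#' @param legs Data frame or matrix with columns `left`, `right` of 0-based
#'   within-replica lattice sites.
#' @param site_bp Lattice site size (bp).
#' @param monomer_bp Monomer size (bp); must be a multiple of `site_bp`.
#' @return Tibble with 0-based `monomer_i < monomer_j`.
#' @export
legs_to_bonds <- function(legs, site_bp = 250, monomer_bp = 2500) {
  if (monomer_bp %% site_bp != 0)
    abort("monomer_bp must be an integer multiple of site_bp")
  legs <- as.data.frame(legs)
  mi <- as.integer((legs$left * site_bp) %/% monomer_bp)
  mj <- as.integer((legs$right * site_bp) %/% monomer_bp)
  keep <- mi != mj
  tibble::tibble(monomer_i = pmin(mi, mj)[keep],
                 monomer_j = pmax(mi, mj)[keep])
}

#' Initial conformation: a (optionally persistent) unit-step random walk
#'
#' With `persistence = 0` this is a plain random walk. A positive
#' `persistence` (in monomers) correlates successive step directions,
#' giving an extended, decondensed fiber — the appropriate starting state
#' for morphology comparisons, since loop-driven condensation is
#' force-driven and fast whereas diffusive decondensation of a compact
#' start is far slower than any desk-scale relaxation.
#'
#' @param n_monomers Chain length.
#' @param seed Optional seed.
#' @param persistence Step-direction correlation length in monomers.
#' @return `n_monomers x 3` coordinate matrix (monomer diameters).
#' @export
init_conformation <- function(n_monomers, seed = NULL, persistence = 0) {
  with_seed_if(seed, {
    g <- matrix(rnorm(3 * n_monomers), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    if (persistence > 0) {
      rho <- exp(-1 / persistence)
      for (i in 2:n_monomers)
        g[i, ] <- rho * g[i - 1, ] + sqrt(1 - rho^2) * g[i, ]
      g <- g / sqrt(rowSums(g^2))
    }
    g[1, ] <- 0
    apply(g, 2, cumsum)
  })
}

#' Advance the bead-spring polymer
#'
#' Overdamped Euler-Maruyama dynamics under backbone springs, extruder-bond
#' springs and soft excluded volume. Chain connectivity is verified after the
#' call; a break raises an integration-instability error advising a smaller
#' `dt_3d`.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param bonds Tibble of 0-based `monomer_i`, `monomer_j` extruder bonds
#'   (may have zero rows).
#' @param config A [polymer_config()].
#' @param n_steps Number of integrator steps.
#' @param seed Optional seed.
#' @return The updated coordinate matrix.
#' @export
advance_polymer <- function(coords, bonds, config, n_steps, seed = NULL) {
  stopifnot(inherits(config, "polymer_config"))
  bm <- if (is.null(bonds) || nrow(bonds) == 0)
    matrix(integer(), ncol = 2)
  else cbind(bonds$monomer_i, bonds$monomer_j)
  if (nrow(bm) > 0 && (min(bm) < 0 || max(bm) >= nrow(coords)))
    abort("bond monomer index outside the chain")
  with_seed_if(seed, cpp_advance_polymer(
    coords, bm, config$k_backbone, config$bond_length,
    config$k_bond, config$bond_rest,
    config$excluded_volume_strength, config$excluded_volume_radius,
    config$dt_3d, as.integer(n_steps), config$f_max, config$disp_max,
    config$confinement_radius, config$confinement_k))
}

#' Capture spatial contacts from a conformation
#'
#' All unordered monomer pairs with Euclidean distance below
#' `capture_radius`, excluding trivial neighbours (`|i - j| <= 1`).
#'
#' @param coords `n x 3` coordinate matrix.
#' @param capture_radius Capture distance (monomer diameters).
#' @return Tibble of 0-based `monomer_i < monomer_j`.
#' @export
capture_contacts <- function(coords, capture_radius = 2) {
  if (capture_radius <= 0) abort("capture_radius must be > 0")
  p <- cpp_capture_contacts(coords, capture_radius, 2L)
  tibble::tibble(monomer_i = p[, 1], monomer_j = p[, 2])
}

#' Couple a lattice trace to the 3D polymer sampler
#'
#' Runs the bead-spring chain for one replica of a lattice trace: extruder
#' bonds are switched instantaneously at each lattice frame, the chain
#' relaxes for `steps_per_frame` integrator steps, and the frame is
#' harvested (conformation kept, contacts captured and accumulated at the
#' monomer level). Monomers bonded in frame t are exactly the coarse-grained
#' extruder legs of lattice frame t.
#'
#' @param trace A `lattice_trace`.
#' @param config A [polymer_config()].
#' @param replicas 1-based replica indices to simulate; a contiguous range
#'   is concatenated into one consecutive 3D chain (extruder legs stay
#'   confined to their 1D replica, but the fiber is continuous), mirroring
#'   the consecutive-replica construction of the reference setup.
#' @param frames Optional integer vector of frame indices to couple
#'   (default: all frames).
#' @param keep_conformations Keep every k-th harvested conformation
#'   (1 keeps all; 0 keeps none).
#' @param seed RNG seed override (default from `config`).
#' @return A `polymer_ensemble` with accumulated monomer-level contact
#'   counts, harvested conformations and per-frame extruder bonds.
#' @export
run_polymer <- function(trace, config = polymer_config(), replicas = 1,
                        frames = NULL, keep_conformations = 1, seed = NULL) {
  stopifnot(inherits(trace, "lattice_trace"), inherits(config, "polymer_config"))
  seed <- if (is.null(seed)) config$seed else seed
  lat <- trace$config
  if (config$monomer_bp %% lat$site_bp != 0)
    abort("monomer_bp must be an integer multiple of site_bp")
  replicas <- sort(as.integer(replicas))
  if (!all(diff(replicas) == 1) || min(replicas) < 1 ||
      max(replicas) > lat$n_replicas)
    abort("replicas must be a contiguous range within the trace")
  n_monomers <- as.integer(length(replicas) * lat$n_sites * lat$site_bp /
                             config$monomer_bp)
  if (is.null(frames)) frames <- seq_along(trace$times)
  per_rep <- trace$n_extruders %/% lat$n_replicas
  cols <- as.vector(vapply(replicas, function(r)
    ((r - 1) * per_rep + 1):(r * per_rep), integer(per_rep)))
  offset <- (min(replicas) - 1) * lat$n_sites

  counts <- matrix(0, n_monomers, n_monomers)
  confs <- list()
  conf_frames <- integer()
  bonds_per_frame <- vector("list", length(frames))

  with_seed_if(seed, {
    coords <- init_conformation(n_monomers,
                                persistence = config$init_persistence)
    first_bonds <- legs_to_bonds(
      data.frame(left = trace$left[frames[1], cols] - offset,
                 right = trace$right[frames[1], cols] - offset),
      lat$site_bp, config$monomer_bp)
    coords <- advance_polymer(coords, first_bonds, config, config$init_steps)
    for (k in seq_along(frames)) {
      f <- frames[k]
      bonds <- legs_to_bonds(
        data.frame(left = trace$left[f, cols] - offset,
                   right = trace$right[f, cols] - offset),
        lat$site_bp, config$monomer_bp)
      bonds_per_frame[[k]] <- bonds
      coords <- advance_polymer(coords, bonds, config, config$steps_per_frame)
      contacts <- capture_contacts(coords, config$capture_radius)
      if (nrow(contacts) > 0) {
        idx <- cbind(contacts$monomer_i + 1L, contacts$monomer_j + 1L)
        counts[idx] <- counts[idx] + 1
      }
      if (keep_conformations > 0 && (k - 1) %% keep_conformations == 0) {
        confs[[length(confs) + 1]] <- coords
        conf_frames <- c(conf_frames, k)
      }
    }
  })
  counts <- counts + t(counts)
  structure(list(contact_counts = counts, n_frames = length(frames),
                 conformations = confs, conf_frames = conf_frames,
                 bonds = bonds_per_frame,
                 n_monomers = n_monomers, config = config,
                 lattice_config = lat, replicas = replicas, seed = seed),
            class = "polymer_ensemble")
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<polymer_ensemble> %d monomers, %d frames, %d kept conformations\n",
    x$n_monomers, x$n_frames, length(x$conformations)))
  invisible(x)
}

#' Aggregate contacts into a binned contact map
#'
#' Accumulates monomer-pair contact counts into genomic bins of `resolution`
#' bp. The result is symmetric; each captured contact contributes one count
#' to both of its mirror entries.
#'
#' @param x A `polymer_ensemble`, or a list of conformations (then contacts
#'   are captured per conformation with `capture_radius`).
#' @param resolution Map resolution in bp (default 10 kb, the scoring
#'   resolution; 2.5 kb is typical for display maps).
#' @param monomer_bp Monomer size in bp (taken from the ensemble when given).
#' @param capture_radius Capture distance, used only for conformation lists.
#' @return A `contact_map` object.
#' @export
aggregate_map <- function(x, resolution = 10000, monomer_bp = 2500,
                          capture_radius = 2) {
  if (inherits(x, "polymer_ensemble")) {
    counts <- x$contact_counts
    monomer_bp <- x$config$monomer_bp
    n_frames <- x$n_frames
  } else {
    if (length(x) < 1) abort("need at least one conformation")
    n <- nrow(x[[1]])
    counts <- matrix(0, n, n)
    for (conf in x) {
      contacts <- capture_contacts(conf, capture_radius)
      if (nrow(contacts) > 0) {
        idx <- cbind(contacts$monomer_i + 1L, contacts$monomer_j + 1L)
        counts[idx] <- counts[idx] + 1
      }
    }
    counts <- counts + t(counts)
    n_frames <- length(x)
  }
  n_monomers <- nrow(counts)
  if (resolution %% monomer_bp != 0)
    abort("resolution must be a multiple of monomer_bp")
  per_bin <- resolution %/% monomer_bp
  n_bins <- ceiling(n_monomers / per_bin)
  group <- (seq_len(n_monomers) - 1L) %/% per_bin + 1L
  agg <- rowsum(t(rowsum(counts, group)), group)
  new_contact_map(agg, resolution, n_frames = n_frames)
}

#' Construct a contact map object
#'
#' @param matrix Symmetric non-negative square matrix of binned counts.
#' @param resolution Bin size in bp.
#' @param n_frames Number of aggregated frames.
#' @return A `contact_map`.
#' @export
new_contact_map <- function(matrix, resolution, n_frames = 1) {
  matrix <- unname(as.matrix(matrix))
  if (nrow(matrix) != ncol(matrix)) abort("contact map must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8 * (1 + max(abs(matrix))))
    abort("contact map must be symmetric")
  structure(list(matrix = matrix, resolution = resolution,
                 n_frames = n_frames),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d bins at %g bp (%d frames, total %g)\n",
              nrow(x$matrix), ncol(x$matrix), x$resolution, x$n_frames,
              sum(x$matrix)))
  invisible(x)
}
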