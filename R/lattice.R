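#' Lattice simulation configuration
#'
#' Parameters of the 1D fixed-timestep loop-extrusion simulation. The
#' reference configuration mirrors the wild-type scenario the model was built
#' around: 2.5-Mb replicas at 250 bp per lattice site, one extruder loaded
#' per 1000 sites (250 kb), and an extruder lifetime of 22 min. The total
#' loop growth rate is `2 * leg_speed` since both legs extrude; the default
#' leg speed of 75 bp/s sets the unimpeded processivity
#' `2 * leg_speed * tau_E` to ~200 kb, matching experimental estimates for
#' interphase cohesin.
#'
#' When `dt_lattice` is `NULL` it is chosen at run time as the largest step
#' satisfying (i) leg step probability `leg_speed * dt / site_bp <= 0.5` and
#' (ii) flip probability `dt / tau <= 0.1` for the fastest barrier process
#' and the extruder lifetime, so rapid CTCF exchange stays resolved.
#'
#' @param n_sites Lattice sites per replica.
#' @param site_bp Base pairs per lattice site.
#' @param n_replicas Number of independent replicas (separate lattices with
#'   impassable ends).
#' @param extruder_separation Lattice sites per extruder; must divide
#'   `n_sites`. Sets the constant extruder count.
#' @param tau_E Mean extruder lifetime in seconds.
#' @param leg_speed Extrusion rate per leg in bp/s.
#' @param dt_lattice Update timescale in seconds, or `NULL` for automatic.
#' @param burn_in Burn-in in seconds before sampling; default `3 * tau_E`.
#' @param seed Integer RNG seed recorded in all outputs.
#' @return A `lattice_config` object.
#' @export
lattice_config <- function(n_sites = 10000, site_bp = 250, n_replicas = 10,
                           extruder_separation = 1000, tau_E = 1320,
                           leg_speed = 75, dt_lattice = NULL,
                           burn_in = NULL, seed = 1L) {
  if (n_sites %% extruder_separation != 0)
    abort("extruder_separation must divide n_sites")
  if (tau_E <= 0 || leg_speed <= 0) abort("tau_E and leg_speed must be > 0")
  structure(list(n_sites = as.integer(n_sites), site_bp = site_bp,
                 n_replicas = as.integer(n_replicas),
                 extruder_separation = as.integer(extruder_separation),
                 tau_E = tau_E, leg_speed = leg_speed,
                 dt_lattice = dt_lattice,
                 burn_in = if (is.null(burn_in)) 3 * tau_E else burn_in,
                 seed = as.integer(seed)),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat("<lattice_config>\n")
  cat(sprintf("  %d replicas x %d sites x %g bp (%.3g Mb each)\n",
              x$n_replicas, x$n_sites, x$site_bp,
              x$n_sites * x$site_bp / 1e6))
  cat(sprintf("  extruders: 1 per %d sites, tau_E = %g s, leg speed = %g bp/s\n",
              x$extruder_separation, x$tau_E, x$leg_speed))
  invisible(x)
}

resolve_dt <- function(config, tau_b, tau_u) {
  dt <- config$dt_lattice
  taus <- c(config$tau_E, tau_b, tau_u[tau_u > 0])
  taus <- taus[is.finite(taus)]
  cap <- if (length(taus) > 0) min(taus) / 10 else Inf
  if (is.null(dt)) {
    dt <- min(0.5 * config$site_bp / config$leg_speed, cap)
  } else if (dt > cap) {
    warn(sprintf(
      "dt_lattice = %g exceeds min(tau)/10 = %g; barrier kinetics may be under-resolved",
      dt, cap))
  }
  p_step <- config$leg_speed * dt / config$site_bp
  if (p_step > 1 || any(dt / tau_b > 1) || any(dt / tau_u[tau_u > 0] > 1))
    abort("invalid-timestep error: a per-update probability dt/tau exceeds 1")
  dt
}

# expand a single-replica layout across all replicas (identical copies),
# returning global 0-based sites, blocking directions and timescales
expand_barriers <- function(layout, config) {
  site <- barrier_sites(layout, config$site_bp)
  if (any(site < 0 | site >= config$n_sites))
    abort("barrier sites fall outside the replica")
  reps <- seq_len(config$n_replicas) - 1L
  tibble::tibble(
    replica = rep(reps, each = nrow(layout)),
    site = rep(site, times = config$n_replicas) +
      rep(reps * config$n_sites, each = nrow(layout)),
    dir = rep(ifelse(layout$strand == "+", 1L, -1L), config$n_replicas),
    tau_b = rep(layout$tau_b, config$n_replicas),
    tau_u = rep(layout$tau_u, config$n_replicas)
  )
}

#' Run the 1D lattice loop-extrusion simulation
#'
#' Simulates dynamic barriers (telegraph switching), extruder turnover with
#' instant uniform reloading, and independent leg stepping, then returns the
#' post-burn-in trace of leg positions and barrier states. Per update the
#' order is: barrier flips, extruder unbind/reload, leg steps in random
#' order. Barrier states start from independent stationary draws
#' (bound with probability `occupancy(tau_b, tau_u)`), so the burn-in only
#' needs to relax the extruder loop-size distribution. Runs are
#' deterministic given `seed`.
#'
#' @param config A [lattice_config()].
#' @param barriers Barrier layout tibble for one replica; it is replicated
#'   identically across all replicas.
#' @param duration Total simulated seconds, including burn-in.
#' @param sample_every Sampling interval in seconds.
#' @param burn_in Burn-in override in seconds (default from `config`).
#' @param seed RNG seed override (default from `config`).
#' @param static Logical; when `TRUE` barrier states are frozen at their
#'   stationary initial draw (the static-barrier comparison model in which a
#'   site with occupancy `o` is permanently bound with probability `o`).
#' @return A `lattice_trace` object with elements `times`, `left`, `right`
#'   (frames x extruders matrices of 0-based global sites), `barrier_states`
#'   (frames x barriers), the expanded `barriers` table, `config` and `seed`.
#' @export
run_lattice <- function(config, barriers, duration, sample_every,
                        burn_in = NULL, seed = NULL, static = FALSE) {
  stopifnot(inherits(config, "lattice_config"))
  burn_in <- if (is.null(burn_in)) config$burn_in else burn_in
  seed <- if (is.null(seed)) config$seed else seed
  if (duration <= burn_in)
    abort("empty-trace error: duration must exceed the burn-in")
  bar <- expand_barriers(barriers, config)
  dt <- resolve_dt(config, bar$tau_b, bar$tau_u)
  p_step <- config$leg_speed * dt / config$site_bp
  n_updates <- as.integer(ceiling(duration / dt))
  burn_updates <- as.integer(ceiling(burn_in / dt))
  stride <- max(1L, as.integer(round(sample_every / dt)))
  if ((n_updates - burn_updates) %/% stride < 1)
    abort("empty-trace error: no sample points after burn-in")

  res <- with_seed_if(seed, {
    bound_init <- runif(nrow(bar)) < occupancy(bar$tau_b, bar$tau_u)
    tb <- bar$tau_b
    tu <- bar$tau_u
    if (static) {
      tb <- rep(Inf, nrow(bar))
      tu <- ifelse(bound_init, 0, Inf)
    }
    cpp_run_lattice(config$n_sites, config$n_replicas,
                    config$extruder_separation, config$tau_E, p_step, dt,
                    bar$site, bar$dir, tb, tu, bound_init,
                    n_updates, burn_updates, stride, 10000L)
  })
  structure(list(times = res$times, left = res$left, right = res$right,
                 barrier_states = res$bound, barriers = bar,
                 n_extruders = res$n_extruders, dt = dt,
                 config = config, layout = barriers, seed = seed,
                 static = static),
            class = "lattice_trace")
}

#' @export
print.lattice_trace <- function(x, ...) {
  cat(sprintf(
    "<lattice_trace> %d frames, %d extruders, %d barriers, seed %d\n",
    length(x$times), x$n_extruders, nrow(x$barriers), x$seed))
  invisible(x)
}

# ---- single-update operations on a small explicit state ---------------------
# These R-level steppers define the update semantics on an inspectable state
# and are used for rule-level tests; run_lattice() executes the same rules in
# compiled code.

#' Create an explicit extrusion state
#'
#' Loads the configured number of extruders on uniform-random adjacent free
#' site pairs within each replica and initialises barrier states from their
#' stationary law. The returned state is a list of two tibbles (`extruders`,
#' `barriers`) that [step_barriers()], [recycle_extruders()] and
#' [step_extruders()] evolve one update at a time.
#'
#' @inheritParams run_lattice
#' @param seed Optional seed.
#' @return An `extrusion_state` object.
#' @export
extrusion_state <- function(config, barriers, seed = NULL) {
  bar <- expand_barriers(barriers, config)
  n_total <- config$n_sites * config$n_replicas
  per_rep <- config$n_sites %/% config$extruder_separation
  with_seed_if(seed, {
    occupied <- logical(n_total)
    ex <- purrr::map_dfr(seq_len(config$n_replicas) - 1L, function(r) {
      purrr::map_dfr(seq_len(per_rep), function(k) {
        repeat {
          s <- r * config$n_sites +
            sample.int(config$n_sites - 1L, 1L) - 1L
          if (!occupied[s + 1] && !occupied[s + 2]) break
        }
        occupied[s + 1] <<- TRUE
        occupied[s + 2] <<- TRUE
        tibble::tibble(replica = r, left_leg = s, right_leg = s + 1L,
                       stalled_left = FALSE, stalled_right = FALSE)
      })
    })
    ex$extruder <- seq_len(nrow(ex))
    bar$bound <- runif(nrow(bar)) < occupancy(bar$tau_b, bar$tau_u)
    structure(list(extruders = ex, barriers = bar, config = config),
              class = "extrusion_state")
  })
}

#' Advance barrier telegraph states by one update
#'
#' Each bound barrier unbinds with probability `dt / tau_b`; each unbound
#' barrier binds with probability `dt / tau_u` (probability 1 when
#' `tau_u = 0`, so such a site is effectively always bound). Rebinding is
#' unconditional on extruder positions: a barrier can rebind while inside an
#' extruded loop.
#'
#' @param barriers Tibble with columns `tau_b`, `tau_u`, `bound`.
#' @param dt Timestep in seconds.
#' @return The tibble with updated `bound`.
#' @export
step_barriers <- function(barriers, dt) {
  if (dt <= 0) abort("dt must be > 0")
  p_unbind <- ifelse(is.infinite(barriers$tau_b), 0, dt / barriers$tau_b)
  p_bind <- ifelse(barriers$tau_u == 0, 1,
                   ifelse(is.infinite(barriers$tau_u), 0,
                          dt / barriers$tau_u))
  if (any(p_unbind > 1) || any(p_bind > 1))
    abort("invalid-timestep error: dt/tau exceeds 1")
  u <- runif(nrow(barriers))
  barriers$bound <- ifelse(barriers$bound, u >= p_unbind, u < p_bind)
  barriers
}

#' Recycle extruders by one update
#'
#' Each extruder unbinds with probability `dt / tau_E` and instantly reloads
#' with both legs on a uniform-random pair of adjacent unoccupied sites in
#' its replica, so the extruder count is conserved. Only currently occupied
#' sites are excluded from loading.
#'
#' @param state An `extrusion_state`.
#' @param dt Timestep in seconds.
#' @param max_tries Bounded retries before a density error.
#' @return The updated state.
#' @export
recycle_extruders <- function(state, dt, max_tries = 10000) {
  cfg <- state$config
  ex <- state$extruders
  occupied <- logical(cfg$n_sites * cfg$n_replicas)
  occupied[c(ex$left_leg, ex$right_leg) + 1L] <- TRUE
  dies <- runif(nrow(ex)) < dt / cfg$tau_E
  for (e in which(dies)) {
    occupied[c(ex$left_leg[e], ex$right_leg[e]) + 1L] <- FALSE
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      s <- ex$replica[e] * cfg$n_sites + sample.int(cfg$n_sites - 1L, 1L) - 1L
      if (!occupied[s + 1] && !occupied[s + 2]) {
        ex$left_leg[e] <- s
        ex$right_leg[e] <- s + 1L
        ex$stalled_left[e] <- FALSE
        ex$stalled_right[e] <- FALSE
        occupied[s + c(1, 2)] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("simulation-density error: no free loading site")
  }
  state$extruders <- ex
  state
}

#' Step extruder legs by one update
#'
#' Each leg attempts one outward step with probability
#' `leg_speed * dt / site_bp`, in random order over all legs. A step is
#' refused silently if the destination site is occupied by another leg, lies
#' beyond the replica boundary, or the leg currently rests on a bound
#' barrier whose orientation blocks its travel direction (so a blocked leg
#' comes to rest ON the barrier site and retries every update). Stall flags
#' record barrier-caused refusals.
#'
#' @inheritParams recycle_extruders
#' @return The updated state.
#' @export
step_extruders <- function(state, dt) {
  cfg <- state$config
  ex <- state$extruders
  bar <- state$barriers
  p_step <- cfg$leg_speed * dt / cfg$site_bp
  if (p_step > 1) abort("invalid-timestep error: step probability exceeds 1")
  n_total <- cfg$n_sites * cfg$n_replicas
  occupied <- logical(n_total)
  occupied[c(ex$left_leg, ex$right_leg) + 1L] <- TRUE
  bar_at <- rep(NA_integer_, n_total)
  bar_at[bar$site + 1L] <- seq_len(nrow(bar))
  legs <- sample(2L * nrow(ex))
  for (l in legs) {
    e <- (l + 1L) %/% 2L
    is_right <- l %% 2L == 0L
    if (runif(1) >= p_step) next
    if (is_right) {
      p <- ex$right_leg[e]; q <- p + 1L
      if (q >= (ex$replica[e] + 1L) * cfg$n_sites || occupied[q + 1L]) next
      b <- bar_at[p + 1L]
      if (!is.na(b) && bar$bound[b] && bar$dir[b] == 1L) {
        ex$stalled_right[e] <- TRUE
        next
      }
      occupied[p + 1L] <- FALSE; occupied[q + 1L] <- TRUE
      ex$right_leg[e] <- q; ex$stalled_right[e] <- FALSE
    } else {
      p <- ex$left_leg[e]; q <- p - 1L
      if (q < ex$replica[e] * cfg$n_sites || occupied[q + 1L]) next
      b <- bar_at[p + 1L]
      if (!is.na(b) && bar$bound[b] && bar$dir[b] == -1L) {
        ex$stalled_left[e] <- TRUE
        next
      }
      occupied[p + 1L] <- FALSE; occupied[q + 1L] <- TRUE
      ex$left_leg[e] <- q; ex$stalled_left[e] <- FALSE
    }
  }
  state$extruders <- ex
  state
}
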