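#' Parameters of the single-extruder loop-size model
#'
#' The analytically tractable layout: one extruder loading between two
#' convergent telegraph barriers separated by `delta` bp, with total loop
#' growth rate `v` (both legs combined, so a midpoint-loaded extruder reaches
#' both barriers at time `delta / v`) and exponential lifetime with mean
#' `tau_E`.
#'
#' @param tau_E Mean extruder lifetime (s).
#' @param tau_b Mean barrier bound time (s); `Inf` allowed.
#' @param tau_u Mean barrier unbound time (s); 0 means permanently bound.
#' @param delta Barrier separation (bp).
#' @param v Total loop growth rate (bp/s).
#' @return A `regime_params` object.
#' @export
regime_params <- function(tau_E, tau_b, tau_u, delta, v) {
  if (tau_E <= 0 || tau_b <= 0 || tau_u < 0 || delta <= 0 || v <= 0)
    abort("invalid parameters: timescales, delta and v must be positive (tau_u >= 0)")
  structure(list(tau_E = tau_E, tau_b = tau_b, tau_u = tau_u,
                 delta = delta, v = v),
            class = "regime_params")
}

#' Classify the kinetic regime of a single extruder lifetime draw
#'
#' Given a realised lifetime, the extruder either (i) never reaches the
#' barrier (`lifetime < delta/v`, "unimpeded"), (ii) can reach it but cannot
#' outlive a typical bound interval (`delta/v < lifetime < delta/v + tau_b`,
#' "blocked-capable"), or (iii) lives long enough to bypass even an occupied
#' barrier after stalling (`lifetime > delta/v + tau_b`, "bypass-capable").
#'
#' @param params A [regime_params()] object.
#' @param lifetime_draw Realised lifetime(s) in seconds (> 0).
#' @return Character vector in
#'   `c("unimpeded", "blocked-capable", "bypass-capable")`.
#' @export
classify_regime <- function(params, lifetime_draw) {
  stopifnot(inherits(params, "regime_params"))
  if (any(lifetime_draw <= 0)) abort("lifetime_draw must be > 0")
  t1 <- params$delta / params$v
  dplyr::case_when(
    lifetime_draw < t1 ~ "unimpeded",
    lifetime_draw < t1 + params$tau_b ~ "blocked-capable",
    TRUE ~ "bypass-capable"
  )
}

#' Closed-form expected loop size between two convergent dynamic barriers
#'
#' For a single extruder loaded at the midpoint, with exponential lifetime
#' (mean `tau_E`) and each leg independently meeting a stationary telegraph
#' barrier at time `delta / v`, the expected extruded length at unbinding is
#'
#' \deqn{E[L] = v \tau_E \left(1 - e^{-\delta/(v\tau_E)}\; o\;
#'   \frac{\tau_b}{\tau_b + \tau_E}\right),\qquad
#'   o = \frac{\tau_b}{\tau_b + \tau_u}.}
#'
#' Sketch: each leg extrudes `v/2 * min(T, delta/v)` before arrival; a leg
#' arriving at a bound barrier (probability `o`, residual bound time
#' exponential with mean `tau_b` by memorylessness) waits, then resumes
#' unimpeded. The expected post-arrival growth per leg is
#' `(v/2) tau_E e^{-delta/(v tau_E)} (1 - o + o tau_E/(tau_E + tau_b))`,
#' and summing the two legs gives the expression above. It recovers
#' `v * tau_E` when occupancy vanishes, the barrier spacing `delta` for
#' permanently bound barriers with `v * tau_E >> delta`, and the
#' linear-in-occupancy static-barrier law when `tau_u >> tau_E`; it is
#' non-increasing in `tau_b` at fixed `tau_u`, with its sharp drop near
#' `tau_b ~ tau_E - delta/v` at short unbound times.
#'
#' @param params A [regime_params()] object.
#' @return Expected loop size in bp.
#' @seealso [mc_loop_oracle()] for the independent event-driven check.
#' @export
expected_loop_size <- function(params) {
  stopifnot(inherits(params, "regime_params"))
  o <- occupancy(params$tau_b, params$tau_u)
  blocked <- if (is.infinite(params$tau_b)) 1 else
    params$tau_b / (params$tau_b + params$tau_E)
  with(params, v * tau_E * (1 - exp(-delta / (v * tau_E)) * o * blocked))
}

#' Monte-Carlo oracle for the single-extruder loop size
#'
#' Direct event-driven simulation: per replicate, an exponential lifetime and
#' a loading position are drawn, and each barrier's telegraph trajectory is
#' simulated explicitly (alternating exponential dwells from a stationary
#' initial state) up to the leg's arrival, so the barrier state and residual
#' bound time at arrival emerge from the trajectory rather than being
#' assumed. Extruder-extruder collisions do not exist in this layout. The
#' final loop size at unbinding is recorded.
#'
#' @param params A [regime_params()] object.
#' @param loading `"midpoint"` (matching the closed form) or `"uniform"`.
#' @param n_replicates Number of replicates (>= 1000).
#' @param seed Optional seed; given a seed the result is reproducible.
#' @return One-row tibble with `mean` (bp), `se`, `n`, `loading`.
#' @export
mc_loop_oracle <- function(params, loading = c("midpoint", "uniform"),
                           n_replicates = 10000, seed = NULL) {
  stopifnot(inherits(params, "regime_params"))
  loading <- match.arg(loading)
  if (n_replicates < 1000) abort("n_replicates must be >= 1000")
  res <- with_seed_if(seed, cpp_mc_loop_oracle(
    as.integer(n_replicates), params$tau_E, params$tau_b, params$tau_u,
    params$delta, params$v, loading == "midpoint"))
  tibble::tibble(mean = res$mean, se = res$se, n = res$n, loading = loading)
}

#' Phase-diagram sweep of expected loop size over barrier timescales
#'
#' Evaluates the closed form (and optionally the oracle) over a grid of
#' `(tau_b, tau_u)` at fixed `delta`, `v`, `tau_E`.
#'
#' @param tau_b,tau_u Numeric vectors of timescales (seconds); the sweep is
#'   their Cartesian product.
#' @param tau_E,delta,v Fixed model parameters.
#' @param oracle_n Replicates for the Monte-Carlo oracle per cell, or `NULL`
#'   to skip the oracle.
#' @param seed Optional seed used for the oracle draws.
#' @return Tibble with `tau_b`, `tau_u`, `occupancy`, `loop_bp` and, when the
#'   oracle runs, `oracle_bp`, `oracle_se`.
#' @export
loop_size_grid <- function(tau_b, tau_u, tau_E = 1320, delta = 87500,
                           v = 500, oracle_n = NULL, seed = NULL) {
  grid <- tidyr::expand_grid(tau_b = tau_b, tau_u = tau_u)
  out <- grid |>
    dplyr::mutate(
      occupancy = occupancy(.data$tau_b, .data$tau_u),
      loop_bp = purrr::map2_dbl(.data$tau_b, .data$tau_u, function(b, u)
        expected_loop_size(regime_params(tau_E, b, u, delta, v)))
    )
  if (!is.null(oracle_n)) {
    oc <- with_seed_if(seed, purrr::map2(out$tau_b, out$tau_u, function(b, u)
      mc_loop_oracle(regime_params(tau_E, b, u, delta, v),
                     "midpoint", oracle_n)))
    out$oracle_bp <- purrr::map_dbl(oc, "mean")
    out$oracle_se <- purrr::map_dbl(oc, "se")
  }
  out
}
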