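#' Constructed morphology fixtures for the vermicelli score
#'
#' Deterministic (given a seed) test conformations with known morphology:
#' `"axial"` arranges the chain as dense loops around a straight central
#' axis with the loop-anchor monomers sitting on the axis (an idealised
#' vermicelli / bottlebrush), while `"coil"` is an equilibrium random-walk
#' chain with sparse random extruder monomers. The axial fixture scores
#' clearly above the coil fixture under [vermicelli_score()].
#'
#' @param kind `"axial"` or `"coil"`.
#' @param n_monomers Chain length (>= 100).
#' @param seed Optional seed.
#' @param loop_len Monomers per loop in the axial fixture.
#' @param loop_radius Radius of the axial fixture's loops (diameters); kept
#'   near the smoothing scale so the wound chain hugs its axis.
#' @return List with `coords` (`n x 3`) and 0-based `extruder_monomers`.
#' @export
morphology_fixture <- function(kind = c("axial", "coil"), n_monomers,
                               seed = NULL, loop_len = 25,
                               loop_radius = 1.5) {
  kind <- match.arg(kind)
  if (n_monomers < 100) abort("n_monomers must be >= 100")
  with_seed_if(seed, {
    if (kind == "axial") {
      m <- seq_len(n_monomers) - 1
      loop <- m %/% loop_len
      phase <- 2 * pi * (m %% loop_len) / loop_len
      # petals through the axis, rotated around it so the tube is centered
      ang <- 2 * pi * loop / 7
      r <- loop_radius * (1 - cos(phase))           # 0 at anchors
      coords <- cbind(r * cos(ang), r * sin(ang),
                      loop * 0.8 + 0.8 * (m %% loop_len) / loop_len) +
        matrix(rnorm(3 * n_monomers, sd = 0.15), ncol = 3)
      extruders <- m[m %% loop_len == 0]
    } else {
      coords <- init_conformation(n_monomers)
      extruders <- sort(sample.int(n_monomers, max(2, n_monomers %/% 100)) - 1L)
    }
    list(coords = coords, extruder_monomers = as.integer(extruders))
  })
}
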