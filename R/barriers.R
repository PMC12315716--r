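#' Stationary occupancy of a telegraph barrier
#'
#' A CTCF site alternating between a bound state (mean dwell `tau_b` seconds)
#' and an unbound state (mean dwell `tau_u` seconds) is bound a stationary
#' fraction `tau_b / (tau_b + tau_u)` of the time. Occupancy alone does not
#' fix the kinetics: many `(tau_b, tau_u)` pairs share one occupancy.
#'
#' @param tau_b Mean bound time in seconds (> 0; `Inf` allowed).
#' @param tau_u Mean unbound time in seconds (>= 0).
#' @return Occupancy in `(0, 1]`, vectorized over inputs.
#' @examples
#' occupancy(1350, 150) # 0.9
#' occupancy(10, 0)     # never unbound
#' @export
occupancy <- function(tau_b, tau_u) {
  if (any(!is.finite(tau_b) & !is.infinite(tau_b)) || any(tau_b <= 0))
    abort("domain error: tau_b must be > 0")
  if (any(tau_u < 0)) abort("domain error: tau_u must be >= 0")
  ifelse(is.infinite(tau_b), 1, tau_b / (tau_b + tau_u))
}

barrier_columns <- c("chrom", "start", "end", "name", "score", "strand",
                     "tau_b", "tau_u")

#' Validate and normalise a barrier layout
#'
#' A barrier layout is a BED-like tibble with 0-based half-open coordinates
#' and columns `chrom`, `start`, `end`, `name`, `score` (= occupancy),
#' `strand`, `tau_b`, `tau_u`. Strand encodes the blocking direction:
#' `"+"` blocks rightward-moving extruder legs, `"-"` blocks leftward-moving
#' legs. Each barrier occupies one lattice site (`end - start == site_bp`).
#'
#' @param x Data frame of barrier records.
#' @param site_bp Lattice site size in bp; used to derive the `site` column.
#' @return A tibble with the columns above plus a 0-based `site` index.
#' @export
barrier_layout <- function(x, site_bp = 250) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(barrier_columns, names(x))
  if (length(missing_cols) > 0)
    abort(paste("barrier layout is missing columns:",
                paste(missing_cols, collapse = ", ")))
  if (!all(x$strand %in% c("+", "-")))
    abort("orientation error: strand must be '+' or '-'")
  if (any(x$tau_b <= 0)) abort("tau_b must be > 0")
  if (any(x$tau_u < 0)) abort("tau_u must be >= 0")
  x$site <- x$start %/% site_bp
  if (anyDuplicated(x$site) > 0) abort("barrier positions must be distinct")
  x$score <- occupancy(x$tau_b, x$tau_u)
  dplyr::arrange(x, .data$start)
}

#' Generate a random barrier layout
#'
#' Places `n_barriers` at distinct uniform-random lattice sites of a region,
#' with blocking orientations assigned by `orientation`: `"random"` draws
#' each direction independently with probability 1/2, `"alternating"`
#' alternates along the region, and `"convergent-pairs"` orients consecutive
#' barriers as inward-facing pairs. With the reference geometry (32 barriers
#' in 2.5 Mb) the mean inter-barrier gap, ends included, is about 75 kb.
#'
#' @param region_bp Region length in bp.
#' @param n_barriers Number of barriers (0 gives a no-barrier control layout).
#' @param tau_b,tau_u Bound/unbound timescales in seconds, recycled per site.
#' @param orientation Orientation scheme (see above).
#' @param site_bp Lattice site size in bp.
#' @param chrom Chromosome label used in the BED-like records.
#' @param seed Optional integer; when given the layout is a pure function of
#'   `(arguments, seed)` and the caller's RNG state is untouched.
#' @return A barrier layout tibble (see [barrier_layout()]).
#' @export
random_layout <- function(region_bp, n_barriers, tau_b = 1350, tau_u = 150,
                          orientation = c("random", "alternating",
                                          "convergent-pairs"),
                          site_bp = 250, chrom = "region", seed = NULL) {
  orientation <- match.arg(orientation)
  n_sites <- region_bp %/% site_bp
  if (n_barriers < 0) abort("n_barriers must be >= 0")
  if (n_barriers >= n_sites)
    abort("overcrowded layout: n_barriers must be < region_bp / site_bp")
  if (n_barriers == 0) {
    empty <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), name = character(),
                            score = numeric(), strand = character(),
                            tau_b = numeric(), tau_u = numeric())
    return(barrier_layout(empty, site_bp))
  }
  with_seed_if(seed, {
    sites <- sort(sample.int(n_sites, n_barriers) - 1L)
    strand <- switch(orientation,
      "random" = sample(c("+", "-"), n_barriers, replace = TRUE),
      "alternating" = rep_len(c("+", "-"), n_barriers),
      "convergent-pairs" = rep_len(c("-", "+"), n_barriers)
    )
    barrier_layout(tibble::tibble(
      chrom = chrom,
      start = sites * site_bp,
      end = (sites + 1L) * site_bp,
      name = paste0("barrier_", seq_len(n_barriers)),
      score = occupancy(tau_b, tau_u),
      strand = strand,
      tau_b = tau_b, tau_u = tau_u
    ), site_bp)
  })
}

#' Two convergent barriers flanking a region midpoint
#'
#' The simplified layout for the analytical loop-size model: two barriers
#' separated by `delta` bp, centered in the region, oriented inward so an
#' extruder loaded between them is trapped (the left barrier blocks
#' leftward-moving legs, the right barrier blocks rightward-moving legs).
#'
#' @param delta Barrier separation in bp.
#' @param region_bp Total region length in bp (must exceed `delta`).
#' @inheritParams random_layout
#' @return A two-row barrier layout tibble.
#' @export
convergent_pair <- function(delta, region_bp, tau_b = 1350, tau_u = 150,
                            site_bp = 250, chrom = "region") {
  if (delta >= region_bp) abort("delta must be < region_bp")
  mid <- (region_bp %/% site_bp) %/% 2
  half <- max(1L, as.integer(round(delta / site_bp / 2)))
  sites <- c(mid - half, mid + half)
  barrier_layout(tibble::tibble(
    chrom = chrom,
    start = sites * site_bp,
    end = (sites + 1L) * site_bp,
    name = c("left", "right"),
    score = occupancy(tau_b, tau_u),
    strand = c("-", "+"),
    tau_b = tau_b, tau_u = tau_u
  ), site_bp)
}

#' Lattice sites occupied by barriers
#'
#' @param layout Barrier layout tibble.
#' @param site_bp Lattice site size in bp.
#' @return Integer vector of 0-based lattice site indices.
#' @export
barrier_sites <- function(layout, site_bp = 250) {
  as.integer(layout$start %/% site_bp)
}

#' Convergently oriented barrier pairs
#'
#' All ordered pairs (upstream barrier blocking leftward legs, downstream
#' barrier blocking rightward legs), i.e. pairs facing each other, as used
#' for convergent dot scoring.
#'
#' @param layout Barrier layout tibble.
#' @param resolution Optional map resolution in bp; when given, 1-based map
#'   bin indices `bin_i`, `bin_j` are added.
#' @return Tibble with `start_i`, `start_j`, `distance_bp` (and bins).
#' @export
convergent_pairs <- function(layout, resolution = NULL) {
  layout <- dplyr::arrange(layout, .data$start)
  up <- which(layout$strand == "-")
  dn <- which(layout$strand == "+")
  grid <- tidyr::expand_grid(i = up, j = dn) |>
    dplyr::filter(layout$start[.data$i] < layout$start[.data$j])
  out <- tibble::tibble(
    start_i = layout$start[grid$i],
    start_j = layout$start[grid$j],
    distance_bp = layout$start[grid$j] - layout$start[grid$i]
  )
  if (!is.null(resolution)) {
    out$bin_i <- out$start_i %/% resolution + 1L
    out$bin_j <- out$start_j %/% resolution + 1L
  }
  out
}
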