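#' Map bins containing barriers
#'
#' @param layout Barrier layout tibble.
#' @param resolution Map resolution in bp.
#' @return 1-based bin indices into the contact-map matrix.
#' @export
barrier_bins <- function(layout, resolution = 10000) {
  as.integer(layout$start %/% resolution + 1L)
}

# index sets (pairs) for the three triangular regions around bin b: three
# congruent right triangles with hypotenuse on the main diagonal -- upstream
# (ending at b), downstream (starting at b), and one centered on b (the
# "spanning" region, holding the contacts that cross the boundary). Because
# the triangles are congruent, every genomic distance enters the within and
# between means with identical weight, so the ratio cancels the contact
# distance decay. The first diagonal (|i - j| <= 1) is excluded everywhere.
insulation_regions <- function(b, w) {
  tri <- function(lo) {
    g <- expand.grid(i = lo:(lo + w), j = lo:(lo + w))
    g[g$j - g$i >= 2, ]
  }
  list(within = rbind(tri(b - w), tri(b)),
       between = tri(b - ceiling(w / 2)))
}

#' Triangular insulation score at barrier positions
#'
#' For each barrier bin, the mean contact frequency inside two within-domain
#' triangles (side = `window`, hypotenuses on the map diagonal, upstream and
#' downstream of the barrier) is divided by the mean in a congruent triangle
#' centered on the barrier, whose contacts span the boundary. Using three
#' congruent on-diagonal triangles weights every genomic distance equally in
#' numerator and denominator, so the ratio cancels the distance decay and the
#' score responds to boundary strength alone; the first diagonals are
#' excluded. Scores are averaged across barriers; being a ratio, the score
#' is invariant under uniform rescaling of the map and equals 1 on any map
#' whose contacts depend only on genomic distance.
#'
#' @param map A `contact_map`.
#' @param barrier_bins 1-based bin indices (see [barrier_bins()]); bins
#'   without a full window margin are dropped.
#' @param window Triangle side in bp (default 50 kb); must be a multiple of
#'   the map resolution.
#' @param per_barrier Return the per-barrier tibble instead of the average.
#' @return Mean insulation score, or a tibble with column `insulation` when
#'   `per_barrier = TRUE`. Barriers whose between-triangle mean is zero are
#'   excluded from the average with a warning.
#' @export
insulation_score <- function(map, barrier_bins, window = 50000,
                             per_barrier = FALSE) {
  stopifnot(inherits(map, "contact_map"))
  if (window %% map$resolution != 0)
    abort("window must be a multiple of the map resolution")
  w <- window %/% map$resolution
  n <- nrow(map$matrix)
  bins <- barrier_bins[barrier_bins - w >= 1 & barrier_bins + w <= n]
  if (length(bins) == 0) abort("no barrier bin has full window margins")
  scores <- purrr::map_dbl(bins, function(b) {
    reg <- insulation_regions(b, w)
    within <- mean(map$matrix[as.matrix(reg$within)])
    between <- mean(map$matrix[as.matrix(reg$between)])
    if (between == 0) NA_real_ else within / between
  })
  if (anyNA(scores))
    warn(sprintf("%d barrier(s) with zero between-domain contacts excluded",
                 sum(is.na(scores))))
  if (per_barrier)
    return(tibble::tibble(bin = bins, insulation = scores))
  mean(scores, na.rm = TRUE)
}

#' Convergent dot score versus genomic distance
#'
#' Collects square snippets of the contact map centered on (barrier i,
#' barrier j) pixels for convergently oriented pairs, averages the snippets
#' within logarithmically spaced genomic-distance bins, and scores each bin
#' as the averaged snippet's central pixel divided by the mean of its four
#' corner pixels. The corner controls make the background local, so a
#' uniform stripe through an anchor row/column does not inflate the score.
#'
#' @param map A `contact_map`.
#' @param pairs Tibble with 1-based `bin_i`, `bin_j` anchor bins (see
#'   [convergent_pairs()]); pairs whose snippet does not fit in the map are
#'   dropped.
#' @param snippet Snippet extent in bp (default 80 kb); the snippet spans
#'   the central pixel plus `snippet / 2` on each side.
#' @param n_bins Number of distance bins (default 25).
#' @param dist_min,dist_max Distance range in bp (default 100 kb - 5 Mb),
#'   geometric spacing, right-open bins.
#' @param min_control Minimum mean count per corner-control pixel of the
#'   averaged snippet required to score a bin; a ratio over near-empty
#'   controls is noise, so sparser bins return `NA` and drop out of
#'   [mean_dot_score()].
#' @return A `dot_profile` tibble with per-bin `d_lo`, `d_hi`, `d_mid`,
#'   `n_snippets` and `score` (`NA` where a bin holds no snippets or its
#'   controls are too sparse).
#' @export
dot_profile <- function(map, pairs, snippet = 80000, n_bins = 25,
                        dist_min = 1e5, dist_max = 5e6, min_control = 1) {
  stopifnot(inherits(map, "contact_map"))
  res <- map$resolution
  half <- max(1L, as.integer(round(snippet / 2 / res)))
  n <- nrow(map$matrix)
  edges <- exp(seq(log(dist_min), log(dist_max), length.out = n_bins + 1))
  edges[1] <- dist_min
  edges[n_bins + 1] <- dist_max
  dim_px <- 2L * half + 1L
  sums <- array(0, c(dim_px, dim_px, n_bins))
  cnt <- integer(n_bins)
  for (k in seq_len(nrow(pairs))) {
    bi <- pairs$bin_i[k]; bj <- pairs$bin_j[k]
    if (bi > bj) { tmp <- bi; bi <- bj; bj <- tmp }
    d <- (bj - bi) * res
    if (d < dist_min || d >= dist_max) next
    if (bi - half < 1 || bj + half > n || bi + half >= bj - half) next
    bin <- findInterval(d, edges, rightmost.closed = FALSE)
    if (bin < 1 || bin > n_bins) next
    sums[, , bin] <- sums[, , bin] +
      map$matrix[(bi - half):(bi + half), (bj - half):(bj + half)]
    cnt[bin] <- cnt[bin] + 1L
  }
  ctr <- half + 1L
  score <- purrr::map_dbl(seq_len(n_bins), function(b) {
    if (cnt[b] == 0) return(NA_real_)
    s <- sums[, , b] / cnt[b]
    corners <- c(s[1, 1], s[1, dim_px], s[dim_px, 1], s[dim_px, dim_px])
    if (mean(corners) < min_control) return(NA_real_)
    s[ctr, ctr] / mean(corners)
  })
  out <- tibble::tibble(bin = seq_len(n_bins),
                        d_lo = edges[-(n_bins + 1)], d_hi = edges[-1],
                        d_mid = sqrt(edges[-(n_bins + 1)] * edges[-1]),
                        n_snippets = cnt, score = score)
  structure(out, class = c("dot_profile", class(out)),
            snippet = snippet, resolution = res)
}

#' Distance-averaged dot score
#'
#' Collapses a [dot_profile()] to a single value: the per-bin scores
#' averaged with weights equal to the number of snippets in each bin, so
#' distances contribute in proportion to how many convergent pairs they
#' hold.
#'
#' @param profile A `dot_profile`.
#' @return Snippet-count-weighted mean dot score.
#' @export
mean_dot_score <- function(profile) {
  ok <- !is.na(profile$score) & profile$n_snippets > 0
  if (!any(ok)) abort("all distance bins are empty")
  weighted.mean(profile$score[ok], profile$n_snippets[ok])
}

# separable 3D Gaussian smoothing via dense band-kernel matrix products
gaussian_smooth_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth_dim <- function(a, dim_i) {
    perm <- c(dim_i, setdiff(1:3, dim_i))
    m <- matrix(aperm(a, perm), nrow = dim(a)[dim_i])
    n <- nrow(m)
    K <- matrix(0, n, n)
    for (off in (-half):half) {
      idx <- seq_len(n)
      keep <- idx + off >= 1 & idx + off <= n
      K[cbind(idx[keep], (idx + off)[keep])] <- kern[off + half + 1]
    }
    out <- K %*% m
    aperm(array(out, dim(a)[perm]), order(perm))
  }
  a |> smooth_dim(1) |> smooth_dim(2) |> smooth_dim(3)
}

#' Vermicelli score of a conformation
#'
#' Quantifies the spatial colocalization of extruders and chromatin that
#' characterises the condensed, worm-like (vermicelli) morphology: all
#' monomer positions and the extruder-leg monomer positions are rasterized
#' onto a shared voxel grid (grid bounds = conformation bounding box padded
#' by 3 sigma), both grids are Gaussian-smoothed, and the Pearson
#' correlation over voxels is returned.
#'
#' @param coords `n x 3` conformation (monomer diameters).
#' @param extruder_monomers 0-based indices of monomers holding extruder
#'   legs (both legs of every extruder bond).
#' @param voxel_size Voxel edge (monomer diameters).
#' @param smoothing_sigma Gaussian sigma in voxels.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
vermicelli_score <- function(coords, extruder_monomers, voxel_size = 1,
                             smoothing_sigma = 2) {
  if (nrow(coords) == 0) abort("empty conformation")
  if (length(extruder_monomers) == 0) abort("need at least one extruder monomer")
  pad <- 3 * smoothing_sigma * voxel_size
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)))
  voxelize <- function(xyz) {
    v <- floor(sweep(xyz, 2, lo) / voxel_size) + 1
    v <- pmin(pmax(v, 1), matrix(dims, nrow(v), 3, byrow = TRUE))
    a <- array(0, dims)
    idx <- (v[, 3] - 1) * dims[1] * dims[2] + (v[, 2] - 1) * dims[1] + v[, 1]
    tab <- table(idx)
    a[as.integer(names(tab))] <- as.integer(tab)
    a
  }
  chrom <- gaussian_smooth_3d(voxelize(coords), smoothing_sigma)
  extr <- gaussian_smooth_3d(
    voxelize(coords[extruder_monomers + 1, , drop = FALSE]), smoothing_sigma)
  if (sd(chrom) == 0 || sd(extr) == 0)
    abort("undefined-score error: zero-variance voxel grid")
  cor(as.vector(chrom), as.vector(extr))
}

#' Vermicelli scores across a polymer ensemble
#'
#' Applies [vermicelli_score()] to kept conformations, using each frame's
#' own bonded leg monomers as the extruder positions.
#'
#' @param ensemble A `polymer_ensemble` from [run_polymer()] with kept
#'   conformations.
#' @param every Score every k-th kept conformation.
#' @inheritParams vermicelli_score
#' @return Tibble with `frame` and `score`.
#' @export
vermicelli_scores <- function(ensemble, every = 1, voxel_size = 1,
                              smoothing_sigma = 2) {
  stopifnot(inherits(ensemble, "polymer_ensemble"))
  if (length(ensemble$conformations) == 0)
    abort("ensemble holds no conformations; rerun with keep_conformations > 0")
  keep <- seq(1, length(ensemble$conformations), by = every)
  purrr::map_dfr(keep, function(k) {
    f <- ensemble$conf_frames[k]
    bonds <- ensemble$bonds[[f]]
    mono <- unique(c(bonds$monomer_i, bonds$monomer_j))
    tibble::tibble(frame = f,
                   score = vermicelli_score(ensemble$conformations[[k]],
                                            mono, voxel_size,
                                            smoothing_sigma))
  })
}
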