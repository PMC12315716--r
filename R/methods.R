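#' Tidy a lattice trace into a long tibble
#'
#' @param x A `lattice_trace`.
#' @param ... Unused.
#' @return Tibble with one row per (frame, extruder): `frame`, `time`,
#'   `extruder`, `replica`, `left`, `right` (0-based global sites) and
#'   `loop_bp`.
#' @export
tidy.lattice_trace <- function(x, ...) {
  n_frames <- length(x$times)
  per_rep <- x$n_extruders %/% x$config$n_replicas
  tibble::tibble(
    frame = rep(seq_len(n_frames), times = x$n_extruders),
    time = rep(x$times, times = x$n_extruders),
    extruder = rep(seq_len(x$n_extruders), each = n_frames),
    replica = rep((seq_len(x$n_extruders) - 1L) %/% per_rep + 1L,
                  each = n_frames),
    left = as.vector(x$left),
    right = as.vector(x$right),
    loop_bp = (as.vector(x$right) - as.vector(x$left)) * x$config$site_bp
  )
}

#' One-row summary of a lattice trace
#'
#' @inheritParams tidy.lattice_trace
#' @return Tibble with frame/extruder counts, mean and median loop size and
#'   the mean bound fraction across barriers.
#' @export
glance.lattice_trace <- function(x, ...) {
  loops <- (x$right - x$left) * x$config$site_bp
  tibble::tibble(
    n_frames = length(x$times),
    n_extruders = x$n_extruders,
    n_barriers = nrow(x$barriers),
    mean_loop_bp = mean(loops),
    median_loop_bp = stats::median(loops),
    mean_bound_fraction = if (nrow(x$barriers) > 0)
      mean(x$barrier_states) else NA_real_,
    seed = x$seed
  )
}

#' Tidy a contact map into bin pairs
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return Tibble with 0-based bin starts `start_i`, `start_j` (bp) and
#'   `count`, upper triangle included once.
#' @export
tidy.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  idx <- which(upper.tri(x$matrix, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(start_i = (idx[, 1] - 1) * x$resolution,
                 start_j = (idx[, 2] - 1) * x$resolution,
                 count = x$matrix[idx])
}

#' @export
glance.contact_map <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$matrix), resolution = x$resolution,
                 n_frames = x$n_frames, total_counts = sum(x$matrix))
}

#' Plot a contact map
#'
#' log10-scaled heat map of binned contact counts.
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidy.contact_map(object)
  df2 <- df[df$start_i != df$start_j,
            c("start_j", "start_i", "count")]
  names(df2) <- c("start_i", "start_j", "count")
  df <- rbind(df, df2)
  ggplot2::ggplot(df, ggplot2::aes(.data$start_i / 1e6, .data$start_j / 1e6,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position (Mb)", y = "position (Mb)",
                  fill = "log10 contacts") +
    ggplot2::theme_minimal()
}

#' Plot an in silico ChIP-seq track
#'
#' @param object An `occupancy_track`.
#' @param bin_bp Plot bin size in bp.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_track <- function(object, bin_bp = 2500, ...) {
  site_bp <- attr(object, "site_bp")
  df <- object |>
    dplyr::mutate(pos = (.data$site * site_bp) %/% bin_bp * bin_bp) |>
    dplyr::summarise(count = sum(.data$count), .by = "pos")
  ggplot2::ggplot(df, ggplot2::aes(.data$pos / 1e6, .data$count)) +
    ggplot2::geom_col(width = bin_bp / 1e6) +
    ggplot2::labs(x = "position (Mb)", y = "extruder leg count") +
    ggplot2::theme_minimal()
}

#' Plot a dot-score profile versus genomic distance
#'
#' @param object A `dot_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dot_profile <- function(object, ...) {
  df <- object[!is.na(object$score), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$d_mid / 1e3, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_snippets)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genomic distance (kb)", y = "dot score",
                  size = "snippets") +
    ggplot2::theme_minimal()
}
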