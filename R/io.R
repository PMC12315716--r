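#' Read a barrier layout from a BED-like file
#'
#' The dialect is BED6 plus two numeric columns: chrom, start, end, name,
#' score (occupancy), strand ('+' blocks rightward-moving legs, '-' blocks
#' leftward-moving legs), tau_b, tau_u (seconds). Coordinates are 0-based
#' half-open. `read_barriers(write_barriers(x))` is the identity on records.
#'
#' @param path File path.
#' @param site_bp Lattice site size in bp.
#' @return A barrier layout tibble.
#' @export
read_barriers <- function(path, site_bp = 250) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad) > 0)
    abort(sprintf("parse error at line %d: expected 8 tab-separated fields, found %d",
                  bad[1], lengths(fields)[bad[1]]))
  m <- do.call(rbind, fields)
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-")))
    abort(paste("orientation error: strand must be '+' or '-'",
                "(use '+' for barriers blocking rightward-moving legs)"))
  barrier_layout(tibble::tibble(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = m[, 4], score = as.numeric(m[, 5]), strand = strand,
    tau_b = as.numeric(m[, 7]), tau_u = as.numeric(m[, 8])
  ), site_bp)
}

#' Write a barrier layout to a BED-like file
#'
#' @param layout Barrier layout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barriers <- function(layout, path) {
  out <- dplyr::arrange(layout, .data$start)
  readr::write_tsv(out[, c("chrom", "start", "end", "name", "score",
                           "strand", "tau_b", "tau_u")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Export an occupancy track as bedGraph
#'
#' Lattice-site counts are summed into bins of `bin_bp` and written as
#' sorted 0-based half-open bedGraph intervals.
#'
#' @param track An `occupancy_track`.
#' @param path Output path.
#' @param bin_bp Output bin size in bp (multiple of the lattice site size).
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, bin_bp = NULL, chrom = "region") {
  site_bp <- attr(track, "site_bp")
  if (is.null(bin_bp)) bin_bp <- site_bp
  if (bin_bp %% site_bp != 0) abort("bin_bp must be a multiple of site_bp")
  binned <- track |>
    dplyr::mutate(start = (.data$site * site_bp) %/% bin_bp * bin_bp) |>
    dplyr::summarise(count = sum(.data$count), .by = "start") |>
    dplyr::arrange(.data$start)
  out <- tibble::tibble(chrom = chrom, start = binned$start,
                        end = binned$start + bin_bp, value = binned$count)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write / read a contact map as a plain-text matrix
#'
#' Dense TSV with `#` header lines carrying resolution and frame count, so
#' maps round-trip losslessly through text.
#'
#' @param map A `contact_map`.
#' @param path File path.
#' @return `write_map` returns `path` invisibly; `read_map` a `contact_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# resolution=%g", map$resolution),
               sprintf("# n_frames=%d", map$n_frames)), con)
  utils::write.table(map$matrix, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  header <- readLines(path, n = 2)
  resolution <- as.numeric(sub("# resolution=", "", header[1], fixed = TRUE))
  n_frames <- as.integer(sub("# n_frames=", "", header[2], fixed = TRUE))
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  new_contact_map(m, resolution, n_frames)
}

#' Save / load simulation containers
#'
#' Traces and polymer ensembles are stored as single-object RDS containers;
#' the full configuration and seed travel inside the object.
#'
#' @param x A `lattice_trace` or `polymer_ensemble`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the object.
#' @export
write_trace <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) readRDS(path)

#' Write a scalar-score report as TSV
#'
#' @param scores Named list or one-row data frame of scalar results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(as.list(scores)), path)
  invisible(path)
}
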