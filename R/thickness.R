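#' Local wall thickness by the largest-inscribed-sphere definition
#'
#' For every foreground voxel the local thickness is the diameter of the
#' largest sphere fully contained in the foreground that still contains that
#' voxel's center. Computed exactly via a Euclidean distance transform
#' followed by descending-radius sphere stamping (the Hildebrand-Ruegsegger
#' scheme): with `dt(c)` the center-to-background Euclidean distance, a
#' sphere centred at `c` covers every voxel strictly closer than `dt(c)`,
#' and the diameter assigned to a voxel is `2 * max(dt) - 1` voxels over all
#' spheres covering it — voxels being unit cubes, the subtraction converts
#' center-to-center distance to material thickness, so a 5-voxel slab
#' measures exactly 5 voxels. Volume boundaries count as background.
#'
#' @param mask a [cs_mask()] with isotropic voxels and nonempty foreground.
#' @return a `cs_thickness_map`: list with `values` (array, micrometres on
#'   foreground voxels, `NA` elsewhere) and `voxel_size` (scalar, um).
#' @export
local_thickness <- function(mask) {
  if (!inherits(mask, "cs_mask")) cs_data_error("mask must be a cs_mask")
  vs <- mask$voxel_size
  if (max(vs) - min(vs) > 1e-9 * max(vs))
    cs_data_error(sprintf(
      "thickness analysis requires isotropic voxels; got %s um",
      paste(signif(vs, 6), collapse = " x ")))
  if (sum(mask$data) == 0) cs_data_error("empty mask: no foreground voxels")
  d <- dim(mask$data)
  # pad one background layer so the volume boundary acts as background
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask$data != 0
  dt2 <- cs_edt_sq(as.logical(padded), dim(padded))
  r <- sqrt(dt2)
  r[!padded] <- 0
  th <- cs_thickness_stamp(r, dim(padded))
  th <- array(th, dim(padded))[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  vals <- (2 * th - 1) * vs[1]
  vals[mask$data == 0] <- NA_real_
  structure(list(values = vals, voxel_size = vs[1]),
            class = "cs_thickness_map")
}

#' @export
print.cs_thickness_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<cs_thickness_map> %d foreground voxels @ %g um; thickness median %.1f um, range [%.1f, %.1f]\n",
    length(v), x$voxel_size, median(v), min(v), max(v)))
  invisible(x)
}

#' Histogram of a thickness map
#'
#' Half-open bins `[e, e + w)` starting at 0; counts conserve the foreground
#' voxel total.
#'
#' @param map a `cs_thickness_map` from [local_thickness()].
#' @param bin_width bin width in micrometres (default one voxel equivalent).
#' @return a `cs_thickness_hist`: list with `bin_edges` (length
#'   `nbins + 1`) and `counts`.
#' @export
thickness_histogram <- function(map, bin_width = map$voxel_size) {
  if (bin_width <= 0) cs_config_error("bin_width must be > 0")
  v <- map$values[!is.na(map$values)]
  nb <- max(1L, as.integer(floor(max(v) / bin_width)) + 1L)
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  idx <- pmin(nb, floor(v / bin_width) + 1L)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, counts = counts),
            class = "cs_thickness_hist")
}

#' Rank correlation between two thickness distributions
#'
#' Spearman correlation of the per-bin counts of two histograms on identical
#' binning — the comparison used to check automatic against manual
#' segmentations.
#'
#' @param a,b `cs_thickness_hist` objects with identical bin edges.
#' @return Spearman rank correlation in \[-1, 1\].
#' @export
compare_distributions <- function(a, b) {
  if (length(a$bin_edges) != length(b$bin_edges) ||
      max(abs(a$bin_edges - b$bin_edges)) > 1e-9)
    cs_data_error("histograms must share identical binning")
  cor(a$counts, b$counts, method = "spearman")
}

#' Write a thickness histogram as CSV
#' @param hist a `cs_thickness_hist`.
#' @param path output CSV path (columns bin_start_um, bin_end_um, count).
#' @return `path`, invisibly.
#' @export
write_thickness_histogram <- function(hist, path) {
  nb <- length(hist$counts)
  write.csv(data.frame(bin_start_um = hist$bin_edges[seq_len(nb)],
                       bin_end_um = hist$bin_edges[seq_len(nb) + 1L],
                       count = hist$counts),
            path, row.names = FALSE)
  invisible(path)
}
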