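#' Canvas geometry
#'
#' The network consumes axial slices on a fixed canvas. Native-resolution
#' volumes are first rescaled in-plane to a unified voxel size (bilinear for
#' intensities, nearest-neighbour for masks), then centred on the canvas by
#' zero-padding or centre-cropping. The default canvas (1792 x 1280 pixels at
#' 6 um) accommodates whole embryo-head cross-sections without losing
#' relevant structure.
#'
#' @param height,width canvas size in pixels; each must be divisible by
#'   `2^depth` of the paired network.
#' @param target_voxel unified in-plane voxel size in micrometres.
#' @return a `cs_canvas` object.
#' @export
canvas_spec <- function(height = 1792, width = 1280, target_voxel = 6) {
  if (height < 1 || width < 1) cs_config_error("canvas dimensions must be >= 1")
  if (target_voxel <= 0) cs_config_error("target_voxel must be > 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_voxel = as.numeric(target_voxel)),
            class = "cs_canvas")
}

empty_grid_transform <- function() {
  list(scale = c(1, 1), native_shape = NULL, scaled_shape = NULL,
       canvas_shape = NULL, pad = c(0L, 0L, 0L, 0L), crop = c(0L, 0L, 0L, 0L),
       native_voxel = NULL, target_voxel = NULL)
}

#' Rescale a volume in-plane to a target voxel size
#'
#' Each axial slice is resampled by bilinear interpolation (nearest-neighbour
#' when `vol` is a mask, so labels stay binary). The slice axis is never
#' resampled; slice spacing is carried as metadata.
#'
#' @param vol a [cs_volume()] or [cs_mask()].
#' @param target_voxel target in-plane voxel size, micrometres.
#' @return list with elements `volume` (resampled) and `transform` (a grid
#'   transform recording the scale factors, serializable with
#'   [grid_transform_to_json()] and invertible with [invert_grid_transform()]).
#' @export
rescale_voxels <- function(vol, target_voxel) {
  if (target_voxel <= 0) cs_config_error("target_voxel must be > 0")
  is_mask <- inherits(vol, "cs_mask")
  d <- dim(vol$data)
  vs <- vol$voxel_size
  s <- vs[2:3] / target_voxel  # output size multiplier per in-plane axis
  out_shape <- c(d[1], max(1L, as.integer(round(d[2] * s[1]))),
                 max(1L, as.integer(round(d[3] * s[2]))))
  gt <- empty_grid_transform()
  gt$scale <- s
  gt$native_shape <- d
  gt$scaled_shape <- out_shape
  gt$native_voxel <- vs
  gt$target_voxel <- target_voxel
  if (all(abs(s - 1) < 1e-12)) {
    out <- vol
  } else {
    arr <- array(0, out_shape)
    maps <- resample_maps(d[2:3], out_shape[2:3])
    for (k in seq_len(d[1]))
      arr[k, , ] <- cs_warp(vol$data[k, , ], maps$mr, maps$mc,
                            bilinear = !is_mask, fill = 0)
    out <- if (is_mask) cs_mask(round(arr), c(vs[1], target_voxel, target_voxel))
           else cs_volume(arr, c(vs[1], target_voxel, target_voxel), vol$dtype_origin)
  }
  out$voxel_size <- c(vs[1], target_voxel, target_voxel)
  list(volume = out, transform = gt)
}

# Centre-aligned coordinate maps for resampling a (h, w) slice to (ho, wo).
resample_maps <- function(from, to) {
  sr <- from[1] / to[1]
  sc <- from[2] / to[2]
  r <- (seq_len(to[1]) - 0.5) * sr - 0.5
  c <- (seq_len(to[2]) - 0.5) * sc - 0.5
  list(mr = matrix(r, to[1], to[2]), mc = matrix(c, to[1], to[2], byrow = TRUE))
}

pad_crop_amounts <- function(n, target) {
  if (target >= n) {
    extra <- target - n
    low <- extra %/% 2L
    c(pad = c(low, extra - low), crop = c(0L, 0L))
  } else {
    extra <- n - target
    low <- extra %/% 2L
    c(pad = c(0L, 0L), crop = c(low, extra - low))
  }
}

#' Centre a volume on the canvas
#'
#' Slices larger than the canvas are centre-cropped; smaller ones are
#' zero-padded symmetrically, the extra pixel of an odd remainder going to
#' the high side. Voxel values inside the placed region are preserved
#' untouched.
#'
#' @param vol a [cs_volume()] or [cs_mask()] already at the canvas voxel size.
#' @param canvas a [canvas_spec()].
#' @param transform optionally, the transform from [rescale_voxels()] to
#'   extend, so one record can invert the whole geometry.
#' @return list with `volume` and `transform`.
#' @export
fit_to_canvas <- function(vol, canvas, transform = NULL) {
  d <- dim(vol$data)
  gt <- if (is.null(transform)) empty_grid_transform() else transform
  if (is.null(gt$scaled_shape)) gt$scaled_shape <- d
  if (is.null(gt$native_shape)) gt$native_shape <- d
  if (is.null(gt$native_voxel)) gt$native_voxel <- vol$voxel_size
  ar <- pad_crop_amounts(d[2], canvas$height)
  ac <- pad_crop_amounts(d[3], canvas$width)
  gt$pad <- as.integer(c(ar[["pad1"]], ar[["pad2"]], ac[["pad1"]], ac[["pad2"]]))
  gt$crop <- as.integer(c(ar[["crop1"]], ar[["crop2"]], ac[["crop1"]], ac[["crop2"]]))
  gt$canvas_shape <- c(d[1], canvas$height, canvas$width)
  arr <- array(0, gt$canvas_shape)
  src_r <- (1L + gt$crop[1]):(d[2] - gt$crop[2])
  src_c <- (1L + gt$crop[3]):(d[3] - gt$crop[4])
  dst_r <- (1L + gt$pad[1]):(canvas$height - gt$pad[2])
  dst_c <- (1L + gt$pad[3]):(canvas$width - gt$pad[4])
  arr[, dst_r, dst_c] <- vol$data[, src_r, src_c, drop = FALSE]
  out <- if (inherits(vol, "cs_mask")) cs_mask(arr, vol$voxel_size)
         else cs_volume(arr, vol$voxel_size, vol$dtype_origin)
  list(volume = out, transform = gt)
}

#' Invert a recorded grid transform
#'
#' Maps a mask (or volume) from the canvas grid back to the native grid:
#' padding is stripped, cropped margins are refilled with zeros, and the
#' in-plane rescale is undone (nearest-neighbour for masks, bilinear
#' otherwise).
#'
#' @param vol canvas-grid [cs_volume()] or [cs_mask()].
#' @param transform the transform returned by [rescale_voxels()] /
#'   [fit_to_canvas()].
#' @return object of the same class on the native grid.
#' @export
invert_grid_transform <- function(vol, transform) {
  gt <- transform
  d <- dim(vol$data)
  if (!is.null(gt$canvas_shape)) {
    if (!identical(d, as.integer(gt$canvas_shape)) && !identical(as.numeric(d), as.numeric(gt$canvas_shape)))
      cs_data_error("volume shape does not match the transform's canvas shape")
    sh <- gt$scaled_shape
    arr <- array(0, sh)
    src_r <- (1L + gt$pad[1]):(d[2] - gt$pad[2])
    src_c <- (1L + gt$pad[3]):(d[3] - gt$pad[4])
    dst_r <- (1L + gt$crop[1]):(sh[2] - gt$crop[2])
    dst_c <- (1L + gt$crop[3]):(sh[3] - gt$crop[4])
    arr[, dst_r, dst_c] <- vol$data[, src_r, src_c, drop = FALSE]
  } else {
    arr <- vol$data
  }
  is_mask <- inherits(vol, "cs_mask")
  nat <- gt$native_shape
  if (!is.null(nat) && !all(dim(arr)[2:3] == nat[2:3])) {
    out <- array(0, nat)
    maps <- resample_maps(dim(arr)[2:3], nat[2:3])
    for (k in seq_len(nat[1]))
      out[k, , ] <- cs_warp(arr[k, , ], maps$mr, maps$mc,
                            bilinear = !is_mask, fill = 0)
    arr <- out
  }
  vs <- if (!is.null(gt$native_voxel)) gt$native_voxel else vol$voxel_size
  if (is_mask) cs_mask(round(arr), vs) else cs_volume(arr, vs, vol$dtype_origin)
}

#' Serialize / restore a grid transform
#' @param transform a grid transform list.
#' @return `grid_transform_to_json()` a JSON string;
#'   `grid_transform_from_json()` the transform list.
#' @export
grid_transform_to_json <- function(transform) {
  jsonlite::toJSON(transform, auto_unbox = FALSE, digits = NA, null = "null")
}

#' @rdname grid_transform_to_json
#' @param json JSON string or file path produced by [grid_transform_to_json()].
#' @export
grid_transform_from_json <- function(json) {
  gt <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (f in c("pad", "crop")) gt[[f]] <- as.integer(gt[[f]])
  gt
}

#' Standardize a volume to zero mean, unit standard deviation
#'
#' Statistics are computed over the whole volume (not per slice), preserving
#' inter-slice intensity relations.
#'
#' @param vol a [cs_volume()].
#' @return standardized [cs_volume()].
#' @export
standardize <- function(vol) {
  x <- vol$data
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    cs_data_error("cannot standardize a constant volume (zero variance)")
  cs_volume((x - mean(x)) / s, vol$voxel_size, vol$dtype_origin)
}

#' Fill sparse every-k-th-slice annotations by linear interpolation
#'
#' Emulates the annotation protocol in which only every k-th axial slice is
#' labelled by hand: intermediate slices are computed by voxelwise linear
#' blending between the bracketing annotated slices and thresholded at 0.5 to
#' restore binarity. Annotated slices are returned unchanged; trailing slices
#' past the last annotated index copy it.
#'
#' @param annotated a [cs_mask()] whose slices at indices 1, 1+k, 1+2k, ...
#'   carry the annotation (contents of other slices are ignored).
#' @param k annotation stride (k = 1 returns the input unchanged).
#' @return a dense [cs_mask()].
#' @export
interpolate_sparse_labels <- function(annotated, k) {
  if (!is.numeric(k) || k < 1) cs_config_error("k must be an integer >= 1")
  k <- as.integer(k)
  if (k == 1L) return(annotated)
  d <- dim(annotated$data)
  out <- array(0, d)
  anchors <- seq(1L, d[1], by = k)
  out[anchors, , ] <- annotated$data[anchors, , , drop = FALSE]
  for (a in head(anchors, -1L)) {
    b <- min(a + k, d[1])
    if (b %in% anchors) {
      lo <- annotated$data[a, , ]
      hi <- annotated$data[b, , ]
      for (j in seq_len(b - a - 1L)) {
        t <- j / (b - a)
        out[a + j, , ] <- ((1 - t) * lo + t * hi) >= 0.5
      }
    }
  }
  last <- max(anchors)
  if (last < d[1])
    for (j in (last + 1L):d[1]) out[j, , ] <- annotated$data[last, , ]
  cs_mask(out * 1, annotated$voxel_size)
}
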