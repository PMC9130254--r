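#' Segment a native-resolution volume slice by slice
#'
#' Applies the canvas pipeline (in-plane rescale to the canvas voxel size,
#' centre pad/crop, whole-volume standardization), runs the network on every
#' axial slice, thresholds the main head, and inverts the recorded grid
#' transform so the returned mask lives on the input grid. No morphological
#' post-processing is applied; the raw thresholded network output is
#' returned.
#'
#' @param vol a [cs_volume()].
#' @param network a trained `cs_network` whose input size equals the canvas.
#' @param canvas the [canvas_spec()] used in training.
#' @param threshold probability cut for binarization; voxels with
#'   `p >= threshold` become foreground.
#' @param save_probabilities also return the canvas-grid probability volume.
#' @return list with `mask` (a [cs_mask()] on the native grid),
#'   `probability_volume` (canvas-grid [cs_volume()] or `NULL`) and
#'   `per_slice_runtime` (seconds, informational).
#' @export
segment_volume <- function(vol, network, canvas, threshold = 0.5,
                           save_probabilities = FALSE) {
  spec <- network$spec
  if (canvas$height != spec$input_height || canvas$width != spec$input_width)
    cs_config_error(sprintf(
      "canvas %dx%d does not match the network input %dx%d",
      canvas$height, canvas$width, spec$input_height, spec$input_width))
  rv <- rescale_voxels(vol, canvas$target_voxel)
  fv <- fit_to_canvas(rv$volume, canvas, rv$transform)
  sv <- standardize(fv$volume)
  gt <- fv$transform
  d <- dim(sv$data)
  prob <- if (save_probabilities) array(0, d) else NULL
  lab <- array(0, d)
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(d[1])) {
    fw <- net_forward(network, sv$data[k, , ], keep_cache = FALSE, heads = FALSE)
    p <- fw$outputs$main
    if (save_probabilities) prob[k, , ] <- p
    lab[k, , ] <- (p >= threshold) * 1
  }
  runtime <- (proc.time()[["elapsed"]] - t0) / d[1]
  canvas_mask <- cs_mask(lab, sv$voxel_size)
  native_mask <- invert_grid_transform(canvas_mask, gt)
  list(mask = native_mask,
       probability_volume = if (save_probabilities)
         cs_volume(prob, sv$voxel_size, "probability") else NULL,
       per_slice_runtime = runtime)
}
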