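#' Volumetric containers and I/O
#'
#' A `cs_volume` is a 3-D grayscale grid with physical voxel-size metadata;
#' a `cs_mask` is a binary grid on the same lattice. Arrays follow the
#' (axial slice, row, column) axis convention; voxel sizes are micrometres
#' per axis, in the same order.
#'
#' Supported containers: NIfTI-1 (`.nii` / `.nii.gz`, spacing carried in the
#' header in millimetres) and TIFF (multipage file or a directory of
#' numerically sorted single-slice files, spacing carried in a JSON sidecar
#' `<name>.voxelsize.json` with schema `{"voxel_size_um": [z, y, x]}`).
#' Integer data round-trip bit-exactly in both containers.
#'
#' @param data numeric 3-D array, slices x rows x columns.
#' @param voxel_size positive numeric length 1 or 3, micrometres per axis.
#' @param dtype_origin character note on the sample's original on-disk type.
#' @return `cs_volume()` returns a volume object; `cs_mask()` a mask object.
#' @examples
#' v <- cs_volume(array(0L, c(2, 4, 4)), voxel_size = 6)
#' dim(v$data)
#' @export
cs_volume <- function(data, voxel_size, dtype_origin = "unknown") {
  data <- as_array3d(data)
  voxel_size <- check_voxel_size(voxel_size)
  if (any(dim(data) < 1L)) cs_data_error("volume dimensions must all be >= 1")
  if (!all(is.finite(data))) cs_data_error("volume contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size,
                 dtype_origin = dtype_origin),
            class = "cs_volume")
}

#' @rdname cs_volume
#' @export
cs_mask <- function(data, voxel_size) {
  data <- as_array3d(data)
  voxel_size <- check_voxel_size(voxel_size)
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    cs_data_error("mask values must be strictly binary (0/1)")
  structure(list(data = data, voxel_size = voxel_size), class = "cs_mask")
}

as_array3d <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    cs_data_error("data must be a 3-D array (slices x rows x columns)")
  storage.mode(x) <- "double"
  x
}

check_voxel_size <- function(v) {
  if (length(v) == 1L) v <- rep(v, 3L)
  if (length(v) != 3L || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
    cs_data_error("voxel_size must be strictly positive on all three axes")
  as.numeric(v)
}

#' @export
print.cs_volume <- function(x, ...) {
  cat(sprintf("<cs_volume> %s voxels @ %s um, range [%g, %g], origin %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data), x$dtype_origin))
  invisible(x)
}

#' @export
print.cs_mask <- function(x, ...) {
  cat(sprintf("<cs_mask> %s voxels @ %s um, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "voxelsize.json")
  else paste0(tools::file_path_sans_ext(path), ".voxelsize.json")
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a volume from TIFF or NIfTI
#'
#' @param path a NIfTI file, a multipage TIFF, or a directory of single-slice
#'   TIFFs with numerically sorted file names.
#' @param format `"auto"` (from the path), `"tiff"` or `"nifti"`.
#' @return a [cs_volume()].
#' @details NIfTI spacing is read from the header (mm, converted to um);
#'   TIFF spacing from the JSON sidecar. A missing sidecar or a header without
#'   positive spacing is an error naming the missing field.
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) cs_data_error(sprintf("path does not exist: %s", path))
  if (format == "auto") format <- if (is_nifti_path(path)) "nifti" else "tiff"
  if (format == "nifti") read_volume_nifti(path) else read_volume_tiff(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    cs_data_error("NIfTI header is missing positive pixdim spacing (voxel size)")
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) cs_data_error("expected a 3-D NIfTI image")
  arr <- array(as.vector(arr), dim(arr))  # strip niftiImage attributes
  cs_volume(arr, voxel_size = pd[1:3] * 1000, dtype_origin = "nifti")
}

read_volume_tiff <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    cs_data_error(sprintf(
      "missing voxel-size metadata: sidecar '%s' with field 'voxel_size_um' not found", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um))
    cs_data_error(sprintf("sidecar '%s' lacks required field 'voxel_size_um'", sc))
  slices <- if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) cs_data_error(sprintf("no TIFF slices in %s", path))
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    files <- files[order(num, basename(files))]
    lapply(files, function(f) tiff_to_matrix(tiff::readTIFF(f, as.is = TRUE)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, tiff_to_matrix)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    cs_data_error(sprintf(
      "inconsistent slice dimensions in stack: first %dx%d, found %s",
      dims[1, 1], dims[2, 1],
      paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", ")))
  arr <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
  for (k in seq_along(slices)) arr[k, , ] <- slices[[k]]
  cs_volume(arr, voxel_size = meta$voxel_size_um, dtype_origin = "tiff")
}

tiff_to_matrix <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1]  # collapse any extra channel
  m
}

#' Write a volume to TIFF or NIfTI
#'
#' Integer-valued data are stored losslessly (16-bit TIFF, int32 NIfTI);
#' other data are stored as floating point (NIfTI only). Voxel size is
#' persisted (NIfTI header in mm; TIFF JSON sidecar in um).
#'
#' @param vol a [cs_volume()] or [cs_mask()].
#' @param path output file (`.nii`, `.nii.gz`, `.tif`) or directory for a
#'   one-file-per-slice TIFF stack.
#' @param format `"auto"`, `"tiff"`, `"tiff-stack"` (directory) or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "tiff-stack", "nifti")) {
  if (inherits(vol, "cs_mask")) vol <- cs_volume(vol$data, vol$voxel_size, "mask")
  if (!inherits(vol, "cs_volume")) cs_data_error("vol must be a cs_volume or cs_mask")
  if (!is.character(format) || !all(format %in% c("auto", "tiff", "tiff-stack", "nifti")))
    cs_data_error(sprintf(
      "unsupported format '%s'; supported: auto, tiff, tiff-stack, nifti",
      paste(format[1], collapse = "")))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (is_nifti_path(path)) "nifti" else "tiff"
  if (!dir.exists(dirname(path)))
    cs_data_error(sprintf("parent directory does not exist: %s", dirname(path)))
  switch(format,
    nifti = write_volume_nifti(vol, path),
    tiff = write_volume_tiff(vol, path, stack = FALSE),
    `tiff-stack` = write_volume_tiff(vol, path, stack = TRUE))
  invisible(path)
}

write_volume_nifti <- function(vol, path) {
  x <- vol$data
  integerish <- all(x == round(x)) && min(x) >= -2^31 && max(x) < 2^31
  dt <- if (integerish) "int32" else "double"
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- vol$voxel_size / 1000
  RNifti::writeNifti(img, path, datatype = dt)
}

write_volume_tiff <- function(vol, path, stack) {
  x <- vol$data
  if (any(x < 0) || any(x > 65535) || any(x != round(x)))
    cs_data_error("TIFF output supports integer data in [0, 65535]; use NIfTI for float volumes")
  ns <- dim(x)[1]
  if (stack) {
    if (!dir.exists(path)) dir.create(path)
    for (k in seq_len(ns)) {
      tiff::writeTIFF(x[k, , ] / 65535,
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 16)
    }
  } else {
    pages <- lapply(seq_len(ns), function(k) x[k, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
}

#' Read a segmentation mask aligned to a reference volume
#'
#' Any nonzero voxel is binarized to 1; the grid shape is validated against
#' the reference volume.
#'
#' @param path mask file readable by [read_volume()].
#' @param reference the companion [cs_volume()].
#' @return a [cs_mask()].
#' @export
read_mask <- function(path, reference) {
  v <- read_volume(path)
  if (!identical(dim(v$data), dim(reference$data)))
    cs_data_error(sprintf(
      "mask shape (%s) does not match reference volume shape (%s)",
      paste(dim(v$data), collapse = "x"),
      paste(dim(reference$data), collapse = "x")))
  cs_mask((v$data != 0) * 1, voxel_size = reference$voxel_size)
}
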