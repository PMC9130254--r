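test_that("TIFF multipage roundtrip preserves integer grids and voxel size", {
  set.seed(1)
  vol <- cs_volume(array(sample(0:65535, 4 * 5 * 6, TRUE), c(4, 5, 6)),
                   voxel_size = c(6, 6, 6), dtype_origin = "16-bit")
  path <- file.path(tempdir(), "rt.tif")
  write_volume(vol, path, format = "tiff")
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size, vol$voxel_size, tolerance = 1e-9)
})

test_that("one-file-per-slice TIFF stack reads with sidecar voxel size", {
  set.seed(2)
  vol <- cs_volume(array(sample(0:255, 3 * 8 * 8, TRUE), c(3, 8, 8)), 6)
  dirp <- file.path(tempdir(), "stack")
  write_volume(vol, dirp, format = "tiff-stack")
  back <- read_volume(dirp)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size, c(6, 6, 6))
})

test_that("NIfTI roundtrip is bit-exact and the header carries mm spacing", {
  set.seed(3)
  vol <- cs_volume(array(sample(0:65535, 8^3, TRUE), c(8, 8, 8)), 6)
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(vol, path)
  # independent header read: 6 um must be stored as 0.006 mm
  hdr <- RNifti::niftiHeader(RNifti::readNifti(path))
  # the header stores pixdim as float32
  expect_equal(unname(hdr$pixdim[2:4]), rep(0.006, 3), tolerance = 1e-6)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size, c(6, 6, 6), tolerance = 1e-6)
})

test_that("an all-zero volume survives I/O with min = max = 0", {
  vol <- cs_volume(array(0, c(2, 4, 4)), 6)
  path <- file.path(tempdir(), "zero.nii")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(min(back$data), 0)
  expect_equal(max(back$data), 0)
})

test_that("missing voxel-size metadata is an explicit error", {
  set.seed(4)
  vol <- cs_volume(array(sample(0:9, 2 * 4 * 4, TRUE), c(2, 4, 4)), 6)
  path <- file.path(tempdir(), "nometa.tif")
  write_volume(vol, path, format = "tiff")
  file.remove(chondroseg:::sidecar_path(path))
  expect_error(read_volume(path), "voxel_size_um")
})

test_that("inconsistent slice dimensions in a stack are rejected", {
  dirp <- file.path(tempdir(), "badstack")
  dir.create(dirp, showWarnings = FALSE)
  tiff::writeTIFF(matrix(0, 4, 4), file.path(dirp, "slice_1.tif"))
  tiff::writeTIFF(matrix(0, 5, 4), file.path(dirp, "slice_2.tif"))
  jsonlite::write_json(list(voxel_size_um = c(6, 6, 6)),
                       file.path(dirp, "voxelsize.json"))
  expect_error(read_volume(dirp), "inconsistent slice dimensions")
})

test_that("read_mask binarizes labels and validates shape", {
  ref <- cs_volume(array(0, c(3, 6, 6)), 6)
  lab <- cs_volume(array(sample(c(0, 255), 3 * 6 * 6, TRUE), c(3, 6, 6)), 6)
  path <- file.path(tempdir(), "mask.nii")
  write_volume(lab, path)
  m <- read_mask(path, ref)
  expect_true(all(m$data %in% c(0, 1)))
  expect_identical(m$data == 1, lab$data == 255)

  wrong <- cs_volume(array(0, c(2, 6, 6)), 6)
  path2 <- file.path(tempdir(), "wrong.nii")
  write_volume(wrong, path2)
  expect_error(read_mask(path2, ref), "2x6x6.*3x6x6")

  empty <- cs_volume(array(0, c(3, 6, 6)), 6)
  path3 <- file.path(tempdir(), "empty.nii")
  write_volume(empty, path3)
  expect_equal(sum(read_mask(path3, ref)$data), 0)
})

test_that("unsupported write formats are refused with the supported list", {
  vol <- cs_volume(array(0, c(2, 4, 4)), 6)
  expect_error(write_volume(vol, file.path(tempdir(), "x.foo"), format = "hdf5"),
               "supported")
})

test_that("float data require NIfTI and roundtrip through it", {
  vol <- cs_volume(array(rnorm(2 * 4 * 4), c(2, 4, 4)), 6)
  expect_error(write_volume(vol, file.path(tempdir(), "f.tif"), format = "tiff"),
               "NIfTI")
  path <- file.path(tempdir(), "f.nii.gz")
  write_volume(vol, path)
  expect_equal(read_volume(path)$data, vol$data, tolerance = 1e-12)
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(cs_volume(array(0, c(2, 2, 2)), voxel_size = c(6, -1, 6)),
               "positive")
  expect_error(cs_volume(array(c(1, NA), c(2, 1, 1)), 6), "finite")
  expect_error(cs_mask(array(c(0, 2), c(2, 1, 1)), 6), "binary")
})
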