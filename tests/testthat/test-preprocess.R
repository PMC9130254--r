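test_that("rescale at the native voxel size is the identity", {
  vol <- cs_volume(array(rnorm(4 * 10 * 10), c(4, 10, 10)), 6)
  rv <- rescale_voxels(vol, 6)
  expect_equal(rv$volume$data, vol$data)
  expect_equal(rv$transform$scale, c(1, 1))
})

test_that("halving the voxel size doubles the in-plane dimensions", {
  vol <- cs_volume(array(rnorm(2 * 10 * 10), c(2, 10, 10)), 12)
  rv <- rescale_voxels(vol, 6)
  expect_equal(dim(rv$volume$data), c(2L, 20L, 20L))
  expect_equal(rv$volume$voxel_size, c(12, 6, 6))
})

test_that("upsampling matches a hand-computed bilinear evaluation", {
  sl <- matrix(c(0, 2, 1, 3), 2, 2)  # [[0,1],[2,3]] by row
  vol <- cs_volume(array(sl, c(1, 2, 2)), 12)
  rv <- rescale_voxels(vol, 6)
  # centre-aligned source coords for output pixel i (0-based): (i+0.5)/2-0.5;
  # outside the grid the interpolant mixes with the zero fill
  bil <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    val <- function(ri, ci) if (ri >= 0 && ri <= 1 && ci >= 0 && ci <= 1)
      sl[ri + 1, ci + 1] else 0
    fr <- r - r0; fc <- c - c0
    (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
      fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
  }
  expected <- outer(0:3, 0:3, Vectorize(function(i, j)
    bil((i + 0.5) / 2 - 0.5, (j + 0.5) / 2 - 0.5)))
  expect_equal(rv$volume$data[1, , ], expected, tolerance = 1e-12)
})

test_that("mask rescaling keeps labels strictly binary", {
  set.seed(7)
  m <- cs_mask(array(rbinom(2 * 9 * 9, 1, 0.4), c(2, 9, 9)), 9)
  rv <- rescale_voxels(m, 6)
  expect_true(all(rv$volume$data %in% c(0, 1)))
  expect_s3_class(rv$volume, "cs_mask")
})

test_that("canvas padding centres the slice and preserves every value", {
  canvas <- canvas_spec(32, 24, 6)
  vol <- cs_volume(array(rnorm(3 * 20 * 18), c(3, 20, 18)) + 5, 6)
  fv <- fit_to_canvas(vol, canvas)
  out <- fv$volume$data
  expect_equal(dim(out), c(3L, 32L, 24L))
  expect_equal(out[, 7:26, 4:21], vol$data)   # interior intact
  expect_equal(sum(out) - sum(vol$data), 0)   # border all zero
  # odd remainders put the extra pixel on the high side
  expect_equal(fv$transform$pad, c(6L, 6L, 3L, 3L))
  fv2 <- fit_to_canvas(cs_volume(array(1, c(1, 31, 23)), 6), canvas)
  expect_equal(fv2$transform$pad[1:2], c(0L, 1L))
  expect_equal(fv2$transform$pad[3:4], c(0L, 1L))
})

test_that("oversized slices are centre-cropped to the canvas", {
  canvas <- canvas_spec(16, 12, 6)
  vol <- cs_volume(array(seq_len(1 * 20 * 14), c(1, 20, 14)), 6)
  fv <- fit_to_canvas(vol, canvas)
  expect_equal(dim(fv$volume$data), c(1L, 16L, 12L))
  expect_equal(fv$volume$data[1, , ], vol$data[1, 3:18, 2:13])
})

test_that("the recorded transform inverts the pad path exactly", {
  canvas <- canvas_spec(32, 32, 6)
  vol <- cs_volume(array(rnorm(2 * 20 * 26), c(2, 20, 26)), 6)
  fv <- fit_to_canvas(vol, canvas)
  back <- invert_grid_transform(fv$volume, fv$transform)
  expect_equal(back$data, vol$data)
})

test_that("rescale-then-fit inverts to the native grid with high mask overlap", {
  ph <- generate_phantom(phantom_preset("desk", seed = 31))
  mask <- cs_mask(ph$truth$data, 9)  # pretend 9 um native voxels
  canvas <- canvas_spec(64, 64, 6)
  rv <- rescale_voxels(mask, 6)
  fv <- fit_to_canvas(rv$volume, canvas, rv$transform)
  back <- invert_grid_transform(fv$volume, fv$transform)
  expect_equal(dim(back$data), dim(mask$data))
  expect_gte(dice_coefficient(back, mask), 0.99)
  # round-tripped JSON serialization drives the same inversion
  gt2 <- grid_transform_from_json(grid_transform_to_json(fv$transform))
  back2 <- invert_grid_transform(fv$volume, gt2)
  expect_equal(back2$data, back$data)
})

test_that("standardize yields mean 0, sd 1, is affine-invariant and idempotent", {
  set.seed(8)
  vol <- cs_volume(array(rnorm(4 * 12 * 12, 100, 25), c(4, 12, 12)), 6)
  sv <- standardize(vol)
  expect_lt(abs(mean(sv$data)), 1e-6)
  expect_lt(abs(sd(sv$data) - 1), 1e-6)
  aff <- cs_volume(3.7 * vol$data + 11, 6)
  expect_equal(standardize(aff)$data, sv$data, tolerance = 1e-9)
  expect_equal(standardize(sv)$data, sv$data, tolerance = 1e-6)
  expect_error(standardize(cs_volume(array(5, c(2, 3, 3)), 6)), "constant")
})

test_that("sparse-label interpolation follows the voxelwise 0.5-threshold rule", {
  d <- c(7, 4, 4)
  ann <- array(0, d)
  # identical bracketing slices propagate unchanged
  ann[1, , ] <- 1
  ann[4, , ] <- 1
  ann[7, , ] <- 1
  dense <- interpolate_sparse_labels(cs_mask(ann, 6), 3)
  expect_true(all(dense$data == 1))
  # a pixel set at slice a and unset at slice a+3 follows the linear blend:
  # fractions 2/3 (set) and 1/3 (unset)
  ann2 <- array(0, d)
  ann2[1, 2, 2] <- 1
  dense2 <- interpolate_sparse_labels(cs_mask(ann2, 6), 3)
  expect_equal(dense2$data[2, 2, 2], 1)  # blend 2/3 >= 0.5
  expect_equal(dense2$data[3, 2, 2], 0)  # blend 1/3 < 0.5
  expect_equal(dense2$data[1, , ], ann2[1, , ])  # annotated slice untouched
  # k = 1 is the identity
  m <- cs_mask(array(rbinom(prod(d), 1, 0.5), d), 6)
  expect_equal(interpolate_sparse_labels(m, 1)$data, m$data)
  expect_error(interpolate_sparse_labels(m, 0), "k must be")
})
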