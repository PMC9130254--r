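test_that("phantoms are deterministic given their seed", {
  a <- generate_phantom(phantom_preset("desk", seed = 9))
  b <- generate_phantom(phantom_preset("desk", seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$data, b$truth$data)
  c <- generate_phantom(phantom_preset("desk", seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("truth masks are thin shells occupying under 5% of the volume", {
  # at the generator's default scale; the small desk preset is denser by
  # construction (the same wall thickness against a much smaller volume)
  for (s in c(3, 8)) {
    ph <- generate_phantom(phantom_preset("default", seed = s))
    expect_lt(mean(ph$truth$data), 0.05)
    expect_gt(sum(ph$truth$data), 0)
  }
})

test_that("zero staining quality erases the cartilage-tissue contrast", {
  # effect size between truth voxels and nearby tissue under 0.1 sd,
  # pooled over several seeds
  deltas <- sapply(1:10, function(s) {
    ph <- generate_phantom(phantom_preset("desk", seed = 400 + s,
                                          staining_quality = 0))
    tr <- ph$truth$data == 1
    # matched background: voxels within 2 voxels of the shell, tissue side
    near <- array(FALSE, dim(tr))
    sh <- which(tr, arr.ind = TRUE)
    for (dz in -2:2) {
      ix <- sh
      ix[, 3] <- ix[, 3] + dz
      ok <- ix[, 3] >= 1 & ix[, 3] <= dim(tr)[3]
      near[ix[ok, , drop = FALSE]] <- TRUE
    }
    near <- near & !tr
    (mean(ph$volume$data[tr]) - mean(ph$volume$data[near])) /
      sd(ph$volume$data[near])
  })
  expect_lt(abs(mean(deltas)), 0.1)
})

test_that("mutant severity removes the septum constructively", {
  full <- generate_phantom(phantom_preset("desk", seed = 12, mutant_severity = 0))
  gone <- generate_phantom(phantom_preset("desk", seed = 12, mutant_severity = 1))
  # same seed, so the shells agree; severity 1 strictly removes voxels
  expect_true(all(gone$truth$data <= full$truth$data))
  septum <- sum(full$truth$data) - sum(gone$truth$data)
  expect_gt(septum, 0)
  half <- generate_phantom(phantom_preset("desk", seed = 12, mutant_severity = 0.5))
  expect_true(sum(half$truth$data) < sum(full$truth$data))
  expect_true(sum(half$truth$data) > sum(gone$truth$data))
})

test_that("contrast monotonically improves region separability", {
  sep <- sapply(c(1, 3, 6), function(ctr) {
    mean(sapply(1:4, function(s) {
      ph <- generate_phantom(phantom_preset("desk", seed = 500 + s,
                                            contrast = ctr))
      tr <- ph$truth$data == 1
      head_reg <- ph$volume$data > 15000 & !tr
      abs(mean(ph$volume$data[tr]) - mean(ph$volume$data[head_reg])) /
        sd(ph$volume$data[head_reg])
    }))
  })
  expect_true(all(diff(sep) > 0))
})

test_that("dataset composition mirrors the study database", {
  ds <- generate_dataset(14, base = phantom_preset("desk"), seed = 77)
  comp <- attr(ds, "composition")
  expect_equal(unname(comp["control"]), 10)
  expect_equal(unname(comp["mutant"]), 3)
  expect_equal(unname(comp["poor-staining"]), 1)
  expect_length(ds, 14)
  # reproducible
  ds2 <- generate_dataset(14, base = phantom_preset("desk"), seed = 77)
  expect_identical(ds[[1]]$volume$data, ds2[[1]]$volume$data)
  # single-sample call works and is deterministic
  one <- generate_dataset(1, base = phantom_preset("desk"),
                          n_mutant = 0, n_poor_staining = 0, seed = 3)
  expect_length(one, 1)
})

test_that("generated wall thickness is recovered by the thickness module", {
  ds <- generate_dataset(3, base = phantom_preset("desk"),
                         shell_thickness_range = c(24, 36),
                         n_mutant = 0, n_poor_staining = 0, seed = 13)
  for (p in ds) {
    tm <- local_thickness(p$truth)
    med <- median(tm$values[!is.na(tm$values)])
    expect_gte(med, 24 - 6)
    expect_lte(med, 36 + 6)
  }
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(shell_thickness = 3), "at least one voxel")
  expect_error(phantom_spec(staining_quality = 2), "0, 1")
  expect_error(phantom_spec(mutant_severity = -0.1), "0, 1")
  expect_error(generate_dataset(2, shell_thickness_range = c(36, 24)), "range")
  expect_error(generate_dataset(2, n_mutant = 2, n_poor_staining = 1),
               "exceeds")
})
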