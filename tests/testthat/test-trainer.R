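test_that("sevenfold plans over 14 samples validate 2 and train 12 per fold", {
  ids <- sprintf("s%02d", 1:14)
  plan <- make_folds(ids, 7, seed = 3)
  sizes <- table(plan$assignments)
  expect_length(sizes, 7)
  expect_true(all(sizes == 2))
  expect_setequal(names(plan$assignments), ids)
  # identical seed, identical plan; different seed shuffles
  expect_identical(make_folds(ids, 7, seed = 3), plan)
  expect_false(identical(make_folds(ids, 7, seed = 4)$assignments,
                         plan$assignments))
})

test_that("k equal to the sample count is leave-one-out", {
  ids <- letters[1:5]
  plan <- make_folds(ids, 5, seed = 1)
  expect_true(all(table(plan$assignments) == 1))
  expect_error(make_folds(ids, 6), "exceeds")
})

test_that("near-equal fold sizes when k does not divide n", {
  plan <- make_folds(1:10, 3, seed = 2)
  expect_lte(diff(range(table(plan$assignments))), 1)
})

test_that("slice subsampling reproduces the sentence it encodes", {
  d <- c(1000, 2, 2)
  empty <- cs_mask(array(0, d), 6)
  expect_equal(subsample_slices(empty, subsample_rule(200, 30)),
               c(1L, 201L, 401L, 601L, 801L))
  # foreground occupying slices 101..400 (the 1-based image of 100-399)
  m <- array(0, d)
  m[101:400, 1, 1] <- 1
  got <- subsample_slices(cs_mask(m, 6), subsample_rule(200, 30))
  # brute-force restatement: every 30th index inside the contiguous
  # foreground range, every 200th outside it
  fg_lo <- 101L; fg_hi <- 400L
  expected <- sort(unique(as.integer(c(seq(fg_lo, fg_hi, by = 30),
                                       seq(1L, fg_lo - 1L, by = 200),
                                       seq(fg_hi + 1L, 1000L, by = 200)))))
  expect_identical(got, expected)
  # both strides 1 select every slice
  expect_identical(subsample_slices(cs_mask(m, 6), subsample_rule(1, 1)),
                   seq_len(1000L))
  expect_true(all(diff(got) > 0))
})

test_that("training for zero epochs returns the initial weights", {
  sl <- crisp_phantom_slice()
  net <- build_network(network_spec(64, 64, 2, 4), seed = 1)
  fit <- train_model(net, list(sl), training_config(epochs = 0))
  expect_identical(fit$network$params, net$params)
  expect_equal(nrow(fit$history), 0)
  expect_error(train_model(net, list(), training_config(epochs = 1)), "empty")
})

test_that("the default training configuration matches the published recipe", {
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_true(cfg$amsgrad)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$epochs, 50L)
})

test_that("a tiny network memorizes a single slice within 200 steps", {
  sl <- crisp_phantom_slice()
  spec <- network_spec(64, 64, depth = 1, base_filters = 32,
                       use_deep_supervision = FALSE)
  net <- build_network(spec, seed = 3)
  cfg <- training_config(learning_rate = 1e-4, epochs = 200, batch_size = 1,
                         seed = 3)
  fit <- train_model(net, list(sl), cfg)
  fw <- net_forward(fit$network, sl$image, heads = FALSE)
  expect_gt(dice_coefficient((fw$outputs$main >= 0.5) * 1, sl$mask), 0.99)
})

test_that("training loss decreases on a learnable problem across seeds", {
  sl <- crisp_phantom_slice()
  for (s in 1:3) {
    net <- build_network(network_spec(64, 64, 1, 8,
                                      use_deep_supervision = FALSE), seed = s)
    fit <- train_model(net, list(sl),
                       training_config(learning_rate = 3e-4, epochs = 30,
                                       batch_size = 1, seed = s))
    expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  }
})

test_that("cross-validation produces one deterministic row per sample", {
  ds <- generate_dataset(4, base = phantom_preset("desk"),
                         n_mutant = 0, n_poor_staining = 0, seed = 55)
  samples <- lapply(ds, function(p) list(volume = p$volume, truth = p$truth))
  plan <- make_folds(names(samples), 2, seed = 1)
  spec <- network_spec(64, 64, depth = 2, base_filters = 4)
  cfg <- training_config(learning_rate = 1e-3, epochs = 1, batch_size = 4,
                         seed = 5)
  canvas <- canvas_spec(64, 64, 6)
  rule <- subsample_rule(24, 8)
  tab <- cross_validate(samples, plan, spec, cfg, canvas, rule = rule)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$sample_id, names(samples))
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
  for (id in names(samples))
    expect_equal(tab$fold[tab$sample_id == id],
                 unname(plan$assignments[id]))
  tab2 <- cross_validate(samples, plan, spec, cfg, canvas, rule = rule)
  expect_identical(tab, tab2)
})
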