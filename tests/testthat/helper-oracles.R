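# Independent oracles and small fixture builders used across the suite.

# Brute-force inscribed-sphere local thickness, straight from the
# definition: for every foreground voxel take the largest sphere (any
# center) that contains the voxel's center and lies entirely in the
# foreground; report its diameter with voxels treated as unit cubes
# (diameter = 2 * center-to-background distance - 1). Volume boundaries
# count as background. Implemented with explicit distance matrices,
# independent of the package's EDT + stamping path.
oracle_local_thickness_um <- function(mask_arr, voxel_um) {
  d <- dim(mask_arr)
  fg <- which(mask_arr != 0, arr.ind = TRUE)
  bg <- which(mask_arr == 0, arr.ind = TRUE)
  nf <- nrow(fg)
  dbg <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- fg[i, ]
    d_out <- min(c(v, d + 1L - v))
    d_in <- if (nrow(bg) > 0)
      sqrt(min((bg[, 1] - v[1])^2 + (bg[, 2] - v[2])^2 + (bg[, 3] - v[3])^2))
    else Inf
    dbg[i] <- min(d_out, d_in)
  }
  th <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- fg[i, ]
    dist2 <- (fg[, 1] - v[1])^2 + (fg[, 2] - v[2])^2 + (fg[, 3] - v[3])^2
    covered <- dist2 < dbg^2 - 1e-9
    th[i] <- max(dbg[covered])
  }
  out <- array(NA_real_, d)
  out[mask_arr != 0] <- (2 * th - 1) * voxel_um
  out
}

# Random test masks: unions of a few balls and boxes, never empty.
random_blob_mask <- function(dims, seed) {
  set.seed(seed)
  arr <- array(0, dims)
  n <- sample(2:4, 1)
  for (i in seq_len(n)) {
    ctr <- sapply(dims, function(m) runif(1, 2, m - 1))
    if (runif(1) < 0.5) {
      r <- runif(1, 1, min(dims) / 3)
      g1 <- slice_grid(dims, 1); g2 <- slice_grid(dims, 2); g3 <- slice_grid(dims, 3)
      arr[(g1 - ctr[1])^2 + (g2 - ctr[2])^2 + (g3 - ctr[3])^2 <= r^2] <- 1
    } else {
      half <- sapply(dims, function(m) runif(1, 0.5, m / 4))
      lo <- pmax(1, round(ctr - half)); hi <- pmin(dims, round(ctr + half))
      arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
    }
  }
  if (sum(arr) == 0) arr[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                         ceiling(dims[3] / 2)] <- 1
  arr
}

slice_grid <- function(d, axis) {
  idx <- switch(axis,
    rep(seq_len(d[1]), times = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  array(idx, d)
}

# A digitized ball mask centred in a cubic volume.
ball_mask <- function(n, r) {
  g1 <- slice_grid(c(n, n, n), 1)
  g2 <- slice_grid(c(n, n, n), 2)
  g3 <- slice_grid(c(n, n, n), 3)
  c0 <- (n + 1) / 2
  ((g1 - c0)^2 + (g2 - c0)^2 + (g3 - c0)^2 <= r^2) * 1
}

# Small standardized slice + mask from a crisp phantom, shared by the
# training-oriented tests.
crisp_phantom_slice <- function(seed = 5, frac = 0.5) {
  ph <- generate_phantom(phantom_preset("desk", seed = seed, noise_sd = 100,
                                        contrast = 10, blur_sigma = 0))
  fgs <- apply(ph$truth$data, 1, sum)
  rng <- range(which(fgs > 0))
  k <- round(rng[1] + frac * diff(rng))
  list(image = (ph$volume$data[k, , ] - mean(ph$volume$data)) / sd(ph$volume$data),
       mask = ph$truth$data[k, , ])
}
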