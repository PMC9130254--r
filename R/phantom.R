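#' Synthetic micro-CT phantom specification
#'
#' A phantom emulates the structural situation the segmentation method is
#' built for: a large, bright, soft-tissue "head" (heavy-metal-stained
#' tissue), a thin curved cartilage-like shell whose intensity is only
#' modestly offset from the surrounding tissue, an optional planar
#' septum-like substructure that can be partially or fully removed to mimic
#' mutant morphology, partial-volume blur, and additive noise. Because air
#' outside the head is about as dark as the cartilage itself, a global
#' intensity threshold cannot isolate the shell — the contextual situation
#' that motivates a learned segmentation — while the ground-truth mask is
#' known exactly by construction.
#'
#' @param volume_shape voxels, (slices, rows, columns).
#' @param voxel_size isotropic voxel size, micrometres.
#' @param shell_thickness shell wall thickness in micrometres (scalar).
#' @param contrast cartilage-vs-tissue intensity separation in units of the
#'   background noise standard deviation.
#' @param staining_quality multiplier on the contrast in \[0, 1\]; 1 is a
#'   properly stained sample, values near 0 emulate improper staining.
#' @param mutant_severity fraction of the septum removed, in \[0, 1\].
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units).
#' @param blur_sigma Gaussian partial-volume blur, voxels.
#' @param seed integer; the phantom is deterministic given the seed.
#' @return a `cs_phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(96, 128, 128), voxel_size = 6,
                         shell_thickness = 30, contrast = 4,
                         staining_quality = 1, mutant_severity = 0,
                         noise_sd = 1500, blur_sigma = 0.7, seed = 1L) {
  if (shell_thickness < voxel_size)
    cs_config_error("shell_thickness must be at least one voxel")
  if (contrast < 0) cs_config_error("contrast must be >= 0")
  if (staining_quality < 0 || staining_quality > 1)
    cs_config_error("staining_quality must lie in [0, 1]")
  if (mutant_severity < 0 || mutant_severity > 1)
    cs_config_error("mutant_severity must lie in [0, 1]")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size = as.numeric(voxel_size),
                 shell_thickness = as.numeric(shell_thickness),
                 contrast = as.numeric(contrast),
                 staining_quality = as.numeric(staining_quality),
                 mutant_severity = as.numeric(mutant_severity),
                 noise_sd = as.numeric(noise_sd),
                 blur_sigma = as.numeric(blur_sigma),
                 seed = as.integer(seed)),
            class = "cs_phantom_spec")
}

#' Desk- and full-scale phantom presets
#'
#' `"desk"` renders 48 slices of 64 x 64 pixels — small enough that
#' training, inference and thickness analysis run in seconds to minutes on a
#' single CPU core; `"default"` renders the 96 x 128 x 128 testing scale;
#' `"paper-scale"` renders full 1792 x 1280 canvas slices for integration
#' smoke tests only.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [phantom_spec()].
#' @return a `cs_phantom_spec`.
#' @export
phantom_preset <- function(preset = c("desk", "default", "paper-scale"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(volume_shape = c(48L, 64L, 64L)),
    default = list(volume_shape = c(96L, 128L, 128L)),
    `paper-scale` = list(volume_shape = c(16L, 1792L, 1280L)))
  do.call(phantom_spec, modifyList(base, list(...)))
}

# Smoothly perturbed radius function on the sphere: 1 + sum of low-order
# angular harmonics with random phases.
radius_modulation <- function(theta, phi, amps, ks, ms, ph1, ph2) {
  out <- 1
  for (i in seq_along(amps))
    out <- out + amps[i] * sin(ks[i] * theta + ph1[i]) * cos(ms[i] * phi + ph2[i])
  out
}

#' Generate one phantom
#'
#' Renders the intensity volume and its exact ground-truth mask. The truth
#' mask is the rasterized shell-plus-septum geometry and is fixed before any
#' intensity is drawn, so staining quality, blur and noise never alter it.
#'
#' @param spec a [phantom_spec()].
#' @return a `cs_phantom`: list with `volume` (a [cs_volume()]), `truth`
#'   (a [cs_mask()]) and `spec_used`.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$seed, {
    d <- spec$volume_shape
    vs <- spec$voxel_size
    # coordinate grids (voxel centers), slices = z
    z <- slice_index_grid(d, 1)
    y <- slice_index_grid(d, 2)
    x <- slice_index_grid(d, 3)
    ctr <- (d + 1) / 2 + runif(3, -0.02, 0.02) * d

    # head: large smooth ellipsoid of bright tissue
    head_ax <- d * runif(3, 0.36, 0.42)
    fh <- sqrt(((z - ctr[1]) / head_ax[1])^2 + ((y - ctr[2]) / head_ax[2])^2 +
               ((x - ctr[3]) / head_ax[3])^2)
    head_region <- fh <= 1

    # cartilage shell: deformed concentric ellipsoid mid-surface
    shell_ax <- head_ax * runif(3, 0.52, 0.62)
    dz <- (z - ctr[1]) / shell_ax[1]
    dy <- (y - ctr[2]) / shell_ax[2]
    dx <- (x - ctr[3]) / shell_ax[3]
    rr <- sqrt(dz^2 + dy^2 + dx^2)
    theta <- acos(pmin(1, pmax(-1, ifelse(rr > 0, dz / rr, 1))))
    phi <- atan2(dy, dx)
    namp <- 3L
    rho <- radius_modulation(theta, phi,
                             amps = runif(namp, 0.03, 0.08),
                             ks = sample(2:4, namp, replace = TRUE),
                             ms = sample(2:4, namp, replace = TRUE),
                             ph1 = runif(namp, 0, 2 * pi),
                             ph2 = runif(namp, 0, 2 * pi))
    f <- rr / rho

    w_vox <- spec$shell_thickness / vs
    if (w_vox < 1) cs_config_error("shell thinner than 1 voxel after rasterization")
    # rasterize the mid-surface as the zero-crossing voxels of f - 1, then
    # grow it to the prescribed wall thickness by exact Euclidean distance
    surface <- zero_crossing(f - 1)
    if (!any(surface)) cs_config_error("shell mid-surface fell outside the volume")
    dist_surf <- sqrt(cs_edt_sq(as.logical(!surface), d))
    shell <- array(dist_surf <= (w_vox - 1) / 2 + 0.25, d)

    # septum: axial-sagittal plane patch spanning the shell interior
    septum <- array(FALSE, d)
    if (spec$mutant_severity < 1) {
      half_w <- (w_vox - 1) / 2 + 0.25
      interior <- f < 0.92
      plane <- abs(x - ctr[3]) <= half_w
      # remove the top `severity` fraction along the z (slice) extent
      if (any(interior & plane)) {
        zr <- range(z[interior & plane])
        keep_below <- zr[1] + (1 - spec$mutant_severity) * (zr[2] - zr[1])
        septum <- interior & plane & (z <= keep_below)
      }
    }
    truth <- (shell | septum)

    # intensity rendering: bright tissue, dark air, cartilage offset by
    # contrast * staining_quality noise-sd units below tissue
    mu_tissue <- 20000
    mu_air <- 12000
    delta <- spec$contrast * spec$noise_sd * spec$staining_quality
    img <- array(mu_air, d)
    img[head_region] <- mu_tissue
    # smooth low-frequency tissue texture
    texture <- low_frequency_field(d, sd = 0.5 * spec$noise_sd)
    img <- img + texture
    img[truth] <- mu_tissue - delta + texture[truth]
    img <- array(cs_blur3d(img, d, spec$blur_sigma), d)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
    img <- round(pmax(img, 0))

    structure(list(volume = cs_volume(img, vs, "synthetic-16bit"),
                   truth = cs_mask(truth * 1, vs),
                   spec_used = spec),
              class = "cs_phantom")
  })
}

slice_index_grid <- function(d, axis) {
  idx <- switch(axis,
    `1` = rep(seq_len(d[1]), times = d[2] * d[3]),
    `2` = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    `3` = rep(seq_len(d[3]), each = d[1] * d[2]))
  array(idx, d)
}

# single-sided rasterization of the implicit surface g = 0: voxels with
# g >= 0 that touch a g < 0 voxel across any of the 6 faces (one voxel
# wide, watertight — it is the boundary layer of the region {g >= 0})
zero_crossing <- function(g) {
  d <- dim(g)
  s <- g >= 0
  out <- array(FALSE, d)
  out[-d[1], , ] <- out[-d[1], , ] | (s[-d[1], , ] & !s[-1, , ])
  out[-1, , ] <- out[-1, , ] | (s[-1, , ] & !s[-d[1], , ])
  out[, -d[2], ] <- out[, -d[2], ] | (s[, -d[2], ] & !s[, -1, ])
  out[, -1, ] <- out[, -1, ] | (s[, -1, ] & !s[, -d[2], ])
  out[, , -d[3]] <- out[, , -d[3]] | (s[, , -d[3]] & !s[, , -1])
  out[, , -1] <- out[, , -1] | (s[, , -1] & !s[, , -d[3]])
  out
}

low_frequency_field <- function(d, sd) {
  coarse_d <- pmax(2L, as.integer(ceiling(d / 16)))
  coarse <- array(rnorm(prod(coarse_d), 0, sd), coarse_d)
  fine <- array(0, c(coarse_d[1], d[2], d[3]))
  maps <- resample_maps(coarse_d[2:3], d[2:3])
  for (k in seq_len(coarse_d[1]))
    fine[k, , ] <- cs_warp(coarse[k, , ], maps$mr, maps$mc, TRUE, 0)
  # interpolate along slices
  out <- array(0, d)
  pos <- (seq_len(d[1]) - 0.5) * coarse_d[1] / d[1] + 0.5
  lo <- pmin(coarse_d[1] - 1L, pmax(1L, floor(pos)))
  t <- pmin(1, pmax(0, pos - lo))
  for (k in seq_len(d[1]))
    out[k, , ] <- (1 - t[k]) * fine[lo[k], , ] + t[k] * fine[lo[k] + 1L, , ]
  out
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with per-sample parameters from the given ranges,
#' mirroring the composition of a real study database: a majority of
#' controls, a minority of mutants of moderate-to-severe severity, and
#' (optionally) one or more improperly stained samples.
#'
#' @param n number of phantoms.
#' @param base a [phantom_spec()] whose fields serve as the shared defaults.
#' @param shell_thickness_range wall-thickness range, um, sampled uniformly
#'   per phantom.
#' @param n_mutant number of mutant phantoms (severity drawn in
#'   \[0.4, 1\]); default mirrors a 3-in-14 composition.
#' @param n_poor_staining number of improperly stained phantoms
#'   (staining_quality drawn in \[0, 0.1\]); default mirrors 1 in 14.
#' @param seed master seed; per-sample seeds derive from it.
#' @return named list of `cs_phantom` objects ("sample01", ...), with a
#'   `composition` attribute counting controls, mutants and poorly stained
#'   samples.
#' @export
generate_dataset <- function(n, base = phantom_spec(),
                             shell_thickness_range = c(24, 36),
                             n_mutant = round(3 * n / 14),
                             n_poor_staining = round(n / 14),
                             seed = 1L) {
  if (n < 1) cs_config_error("n must be >= 1")
  if (diff(shell_thickness_range) < 0 ||
      shell_thickness_range[1] < base$voxel_size)
    cs_config_error("invalid shell_thickness_range")
  if (n_mutant + n_poor_staining > n)
    cs_config_error("n_mutant + n_poor_staining exceeds n")
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2L, n)
    thick <- runif(n, shell_thickness_range[1], shell_thickness_range[2])
    sev <- runif(n, 0.4, 1)
    quality <- runif(n, 0, 0.1)
    kind <- rep("control", n)
    if (n_mutant > 0) kind[seq_len(n_mutant)] <- "mutant"
    if (n_poor_staining > 0)
      kind[n_mutant + seq_len(n_poor_staining)] <- "poor-staining"
    kind <- sample(kind)  # shuffle roles over sample indices
    out <- lapply(seq_len(n), function(i) {
      sp <- base
      sp$seed <- seeds[i]
      sp$shell_thickness <- thick[i]
      if (kind[i] == "mutant") sp$mutant_severity <- sev[i]
      if (kind[i] == "poor-staining") sp$staining_quality <- quality[i]
      generate_phantom(sp)
    })
    names(out) <- sprintf("sample%02d", seq_len(n))
    attr(out, "composition") <- c(control = sum(kind == "control"),
                                  mutant = sum(kind == "mutant"),
                                  `poor-staining` = sum(kind == "poor-staining"))
    out
  })
}
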