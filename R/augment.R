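#' Stochastic two-transform augmentation policy
#'
#' Each training slice undergoes two consecutive transforms drawn jointly
#' from a 6 x 6 probability matrix over the ordered pairs of
#' \{rotation, vflip, gamma, elastic, scaling, none\}. The named preset
#' `"paper2022"` ships the published parameter ranges (rotation -10..10
#' degrees, gamma exponent 0.9..1.1, scaling 0.9..1.1) and joint pair
#' probabilities (e.g. elastic followed by elastic: 0.09).
#'
#' @param rotation_range rotation angle range, degrees.
#' @param gamma_range gamma exponent range.
#' @param scale_range isotropic scale factor range.
#' @param elastic_params list with `spacing` (control-point spacing, px) and
#'   `max_disp` (displacement standard deviation, px) of the random elastic
#'   displacement field.
#' @param pair_probabilities 6 x 6 nonnegative matrix over ordered
#'   (first, second) transform pairs, rows/cols in the order rotation,
#'   vflip, gamma, elastic, scaling, none; must sum to 1 within 1e-9.
#' @return an `cs_aug_policy` object.
#' @export
augmentation_policy <- function(rotation_range = c(-10, 10),
                                gamma_range = c(0.9, 1.1),
                                scale_range = c(0.9, 1.1),
                                elastic_params = list(spacing = 128, max_disp = 10),
                                pair_probabilities = paper_pair_probabilities()) {
  for (rg in list(rotation_range, gamma_range, scale_range))
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2])
      cs_config_error("transform ranges must be finite with low <= high")
  P <- as.matrix(pair_probabilities)
  if (!all(dim(P) == c(6, 6)) || any(P < 0))
    cs_config_error("pair_probabilities must be a nonnegative 6x6 matrix")
  if (abs(sum(P) - 1) > 1e-9)
    cs_config_error(sprintf(
      "pair_probabilities must sum to 1 within 1e-9 (got %.12f)", sum(P)))
  dimnames(P) <- list(cs_transform_names(), cs_transform_names())
  structure(list(rotation_range = rotation_range, gamma_range = gamma_range,
                 scale_range = scale_range, elastic_params = elastic_params,
                 pair_probabilities = P),
            class = "cs_aug_policy")
}

cs_transform_names <- function()
  c("rotation", "vflip", "gamma", "elastic", "scaling", "none")

#' @rdname augmentation_policy
#' @details `paper_pair_probabilities()` returns the published joint matrix;
#'   its 36 entries sum to exactly 1.
#' @export
paper_pair_probabilities <- function() {
  P <- rbind(
    c(0.01, 0.02, 0.01, 0.03, 0.02, 0.01),   # rotation first
    c(0.02, 0.04, 0.02, 0.06, 0.04, 0.02),   # vflip first
    c(0.01, 0.02, 0.01, 0.03, 0.02, 0.01),   # gamma first
    c(0.03, 0.06, 0.03, 0.09, 0.06, 0.03),   # elastic first
    c(0.02, 0.04, 0.02, 0.06, 0.04, 0.02),   # scaling first
    c(0.01, 0.02, 0.01, 0.03, 0.02, 0.01))   # no transform first
  dimnames(P) <- list(cs_transform_names(), cs_transform_names())
  P
}

#' Draw an ordered transform pair with its parameters
#'
#' The ordered (first, second) pair is drawn from the policy's joint matrix;
#' each continuous parameter is then drawn uniformly from its range,
#' independently per transform.
#'
#' @param policy an [augmentation_policy()].
#' @return a `cs_transform_draw`: list with `first`, `second` (transform
#'   names) and `parameters` (named per-slot parameter lists).
#' @export
sample_transform_pair <- function(policy) {
  P <- policy$pair_probabilities
  if (abs(sum(P) - 1) > 1e-9)
    cs_config_error("pair probability matrix does not sum to 1")
  idx <- sample.int(36L, 1L, prob = as.vector(P))
  first <- cs_transform_names()[(idx - 1L) %% 6L + 1L]
  second <- cs_transform_names()[(idx - 1L) %/% 6L + 1L]
  structure(list(first = first, second = second,
                 parameters = list(first = draw_params(first, policy),
                                   second = draw_params(second, policy))),
            class = "cs_transform_draw")
}

draw_params <- function(name, policy) {
  switch(name,
    rotation = list(angle = runif(1, policy$rotation_range[1], policy$rotation_range[2])),
    gamma = list(gamma = runif(1, policy$gamma_range[1], policy$gamma_range[2])),
    scaling = list(scale = runif(1, policy$scale_range[1], policy$scale_range[2])),
    elastic = list(seed = sample.int(.Machine$integer.max - 1L, 1L)),
    list())
}

#' Apply a drawn transform pair to an image/mask slice
#'
#' Geometric transforms (rotation, flip, elastic, scaling) are applied
#' identically to image and mask, with bilinear interpolation for the image
#' and nearest-neighbour for the mask; regions warped in from outside the
#' canvas are filled with 0, matching canvas padding. The gamma transform
#' acts on the image only, on a min-max-normalized copy mapped to \[0, 1\]
#' and restored to the original range afterwards.
#'
#' @param image numeric matrix (a canvas slice).
#' @param mask binary matrix of the same shape.
#' @param draw a `cs_transform_draw` from [sample_transform_pair()].
#' @param policy the [augmentation_policy()] (supplies elastic parameters).
#' @return list with transformed `image` and `mask` (still strictly binary).
#' @export
apply_transform <- function(image, mask, draw, policy) {
  if (!all(dim(image) == dim(mask)))
    cs_data_error("image and mask must have identical shapes")
  for (slot in c("first", "second")) {
    nm <- draw[[slot]]
    par <- draw$parameters[[slot]]
    res <- apply_single_transform(image, mask, nm, par, policy)
    image <- res$image
    mask <- res$mask
  }
  list(image = image, mask = mask)
}

apply_single_transform <- function(image, mask, name, par, policy) {
  d <- dim(image)
  switch(name,
    none = list(image = image, mask = mask),
    vflip = list(image = image[d[1]:1, , drop = FALSE],
                 mask = mask[d[1]:1, , drop = FALSE]),
    gamma = {
      rng <- range(image)
      if (diff(rng) == 0)
        cs_data_error("gamma transform undefined for a constant (degenerate-range) image")
      p <- (image - rng[1]) / diff(rng)
      list(image = p^par$gamma * diff(rng) + rng[1], mask = mask)
    },
    rotation = warp_pair(image, mask, rotation_maps(d, par$angle)),
    scaling = warp_pair(image, mask, scaling_maps(d, par$scale)),
    elastic = warp_pair(image, mask, elastic_maps(d, policy$elastic_params, par$seed)),
    cs_config_error(sprintf("unknown transform '%s'", name)))
}

warp_pair <- function(image, mask, maps) {
  list(image = cs_warp(image, maps$mr, maps$mc, bilinear = TRUE, fill = 0),
       mask = cs_warp(mask, maps$mr, maps$mc, bilinear = FALSE, fill = 0))
}

# Inverse-map coordinate grids (0-based source coords per output pixel).
base_grid <- function(d) {
  list(r = matrix(seq_len(d[1]) - 1, d[1], d[2]),
       c = matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE))
}

rotation_maps <- function(d, angle_deg) {
  th <- angle_deg * pi / 180
  g <- base_grid(d)
  cr <- (d[1] - 1) / 2
  cc <- (d[2] - 1) / 2
  dr <- g$r - cr
  dc <- g$c - cc
  # inverse rotation of the output grid into the source image
  list(mr = cr + cos(th) * dr - sin(th) * dc,
       mc = cc + sin(th) * dr + cos(th) * dc)
}

scaling_maps <- function(d, s) {
  g <- base_grid(d)
  cr <- (d[1] - 1) / 2
  cc <- (d[2] - 1) / 2
  list(mr = cr + (g$r - cr) / s, mc = cc + (g$c - cc) / s)
}

elastic_maps <- function(d, params, seed) {
  with_seed(seed, {
    sp <- max(2, params$spacing)
    nr <- max(2L, as.integer(ceiling(d[1] / sp)) + 1L)
    nc <- max(2L, as.integer(ceiling(d[2] / sp)) + 1L)
    coarse_r <- matrix(rnorm(nr * nc, 0, params$max_disp), nr, nc)
    coarse_c <- matrix(rnorm(nr * nc, 0, params$max_disp), nr, nc)
    maps <- resample_maps(c(nr, nc), d)
    disp_r <- cs_warp(coarse_r, maps$mr, maps$mc, bilinear = TRUE, fill = 0)
    disp_c <- cs_warp(coarse_c, maps$mr, maps$mc, bilinear = TRUE, fill = 0)
    g <- base_grid(d)
    list(mr = g$r + disp_r, mc = g$c + disp_c)
  })
}

#' Augment one training example
#'
#' Draws a fresh transform pair from the policy and applies it:
#' `apply(second, apply(first, .))`.
#'
#' @inheritParams apply_transform
#' @param policy an [augmentation_policy()].
#' @return list with augmented `image` and `mask`.
#' @export
augment_example <- function(image, mask, policy) {
  draw <- sample_transform_pair(policy)
  apply_transform(image, mask, draw, policy)
}
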