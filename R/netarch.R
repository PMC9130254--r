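#' Network specification
#'
#' Describes the residual encoder-decoder used for slice-wise segmentation:
#' a U-shaped topology whose encoder halves the spatial dimensions `depth`
#' times (strided convolution in the convolutional path of each downsampling
#' residual block, max-pooling + 1x1 convolution in the identity path),
#' whose decoder mirrors it with transposed convolutions (nearest-neighbour
#' interpolation + 1x1 convolution in the identity path), with encoder
#' feature maps concatenated into the decoder at matching levels. With deep
#' supervision, every decoder level carries an auxiliary 1x1
#' convolution + sigmoid head whose output is upsampled to ground-truth
#' resolution; the shallowest (full-resolution) head is the main output.
#'
#' At the published scale (1792 x 1280 input, depth 6) the deepest feature
#' maps are 28 x 20 pixels and there are 7 supervised outputs with loss
#' weights, deepest to shallowest, 0.03, 0.05, 0.08, 0.12, 0.15, 0.2, 0.37.
#'
#' @param input_height,input_width canvas slice size in pixels; each must be
#'   divisible by `2^depth`.
#' @param depth number of factor-2 downsampling levels.
#' @param base_filters channels at the top (full-resolution) level.
#' @param filters_double_per_level double the channel count at every
#'   downsampling level (the U-Net convention).
#' @param use_residual residual blocks (identity paths) on/off — ablation
#'   switch.
#' @param use_deep_supervision auxiliary supervised heads on/off — ablation
#'   switch.
#' @param activation `"SELU"` (with LeCun-normal weight initialization) or
#'   `"ReLU"` (with He-normal initialization) — ablation switch.
#' @param supervision_weights `depth + 1` positive loss weights, deepest
#'   head first, summing to 1; `NULL` takes the published weights at depth 6
#'   and a normalized geometric ramp otherwise.
#' @return a `cs_netspec` object.
#' @export
network_spec <- function(input_height = 1792, input_width = 1280, depth = 6,
                         base_filters = 16, filters_double_per_level = TRUE,
                         use_residual = TRUE, use_deep_supervision = TRUE,
                         activation = c("SELU", "ReLU"),
                         supervision_weights = NULL) {
  activation <- match.arg(activation)
  depth <- as.integer(depth)
  if (depth < 1) cs_config_error("depth must be >= 1")
  f <- 2^depth
  if (input_height %% f != 0)
    cs_config_error(sprintf(
      "input height %d is not divisible by 2^%d = %d", input_height, depth, f))
  if (input_width %% f != 0)
    cs_config_error(sprintf(
      "input width %d is not divisible by 2^%d = %d", input_width, depth, f))
  if (is.null(supervision_weights))
    supervision_weights <- default_supervision_weights(depth)
  w <- supervision_weights
  if (length(w) != depth + 1 || any(w <= 0))
    cs_config_error(sprintf(
      "supervision_weights must hold %d positive entries (deepest first)",
      depth + 1))
  if (abs(sum(w) - 1) > 1e-9)
    cs_config_error(sprintf("supervision_weights must sum to 1 (got %.12f)", sum(w)))
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width), depth = depth,
                 base_filters = as.integer(base_filters),
                 filters_double_per_level = isTRUE(filters_double_per_level),
                 use_residual = isTRUE(use_residual),
                 use_deep_supervision = isTRUE(use_deep_supervision),
                 activation = activation,
                 supervision_weights = as.numeric(w)),
            class = "cs_netspec")
}

#' @rdname network_spec
#' @details `default_supervision_weights(6)` returns the published vector;
#'   other depths get a geometric ramp (ratio 1.6, shallowest largest)
#'   normalized to sum 1.
#' @export
default_supervision_weights <- function(depth) {
  if (depth == 6) return(c(0.03, 0.05, 0.08, 0.12, 0.15, 0.2, 0.37))
  w <- 1.6^(0:depth)
  w / sum(w)
}

#' Ablation variants of the published configuration
#'
#' Returns the network spec with exactly one proposed modification removed:
#' `"full"` (nothing removed), `"no_residual"`, `"no_deep_supervision"`,
#' `"relu"` (SELU ablated), `"shallow"` (increased depth ablated: 4 levels),
#' or `"no_augmentation"` (spec unchanged; the trainer drops the policy).
#'
#' @param variant one of the names above.
#' @param base a `cs_netspec` to modify (default: published configuration).
#' @return a `cs_netspec`.
#' @export
ablation_spec <- function(variant = c("full", "no_residual",
                                      "no_deep_supervision", "relu",
                                      "shallow", "no_augmentation"),
                          base = network_spec()) {
  variant <- match.arg(variant)
  s <- unclass(base)
  s$supervision_weights <- NULL
  s <- switch(variant,
    full = s,
    no_augmentation = s,
    no_residual = { s$use_residual <- FALSE; s },
    no_deep_supervision = { s$use_deep_supervision <- FALSE; s },
    relu = { s$activation <- "ReLU"; s },
    shallow = { s$depth <- 4L; s })
  do.call(network_spec, s)
}

channels_at <- function(spec, level) {
  if (spec$filters_double_per_level) spec$base_filters * 2L^level
  else spec$base_filters
}

#' Build the network
#'
#' Allocates and initializes all trainable parameters for the given spec
#' (LeCun normal for SELU, He normal for ReLU; biases zero).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `cs_network`: list with `spec`, `params` (flat named list of
#'   weight matrices/bias vectors) and `layout` (per-layer shapes).
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "cs_netspec")) cs_config_error("spec must be a cs_netspec")
  L <- spec$depth
  layout <- list()
  add_conv <- function(name, kh, kw, cin, cout)
    layout[[name]] <<- list(kind = "conv", kh = kh, kw = kw, cin = cin, cout = cout)
  add_tconv <- function(name, cin, cout)
    layout[[name]] <<- list(kind = "tconv", cin = cin, cout = cout)
  ch <- function(l) channels_at(spec, l)
  res <- spec$use_residual

  # stem: flat block, 1 channel in
  add_conv("enc0.c1", 3, 3, 1, ch(0))
  add_conv("enc0.c2", 3, 3, ch(0), ch(0))
  if (res) add_conv("enc0.id", 1, 1, 1, ch(0))
  for (l in seq_len(L)) {
    add_conv(sprintf("down%d.c1", l), 3, 3, ch(l - 1), ch(l))
    add_conv(sprintf("down%d.c2", l), 3, 3, ch(l), ch(l))
    if (res) add_conv(sprintf("down%d.id", l), 1, 1, ch(l - 1), ch(l))
    add_conv(sprintf("encf%d.c1", l), 3, 3, ch(l), ch(l))
    add_conv(sprintf("encf%d.c2", l), 3, 3, ch(l), ch(l))
  }
  for (l in L:1) {
    add_tconv(sprintf("up%d.t", l), ch(l), ch(l - 1))
    add_conv(sprintf("up%d.c2", l), 3, 3, ch(l - 1), ch(l - 1))
    if (res) add_conv(sprintf("up%d.id", l), 1, 1, ch(l), ch(l - 1))
    add_conv(sprintf("decf%d.c1", l - 1), 3, 3, 2L * ch(l - 1), ch(l - 1))
    add_conv(sprintf("decf%d.c2", l - 1), 3, 3, ch(l - 1), ch(l - 1))
    if (res) add_conv(sprintf("decf%d.id", l - 1), 1, 1, 2L * ch(l - 1), ch(l - 1))
    if (spec$use_deep_supervision && l >= 2)
      add_conv(sprintf("head%d", l - 1), 1, 1, ch(l - 1), 1)
  }
  if (spec$use_deep_supervision) add_conv("head0", 1, 1, ch(0), 1)
  add_conv("main", 1, 1, ch(0), 1)

  params <- with_seed(seed, init_params(layout, spec$activation))
  structure(list(spec = spec, params = params, layout = layout),
            class = "cs_network")
}

init_params <- function(layout, activation) {
  gain <- if (activation == "SELU") 1 else 2  # LeCun vs He normal
  params <- list()
  for (nm in names(layout)) {
    ly <- layout[[nm]]
    if (ly$kind == "conv") {
      fan_in <- ly$kh * ly$kw * ly$cin
      params[[paste0(nm, ".W")]] <-
        matrix(rnorm(fan_in * ly$cout, 0, sqrt(gain / fan_in)), fan_in, ly$cout)
    } else {  # tconv, kernel 2 stride 2: one tap per output unit
      fan_in <- ly$cin
      params[[paste0(nm, ".W")]] <-
        matrix(rnorm(ly$cin * 4 * ly$cout, 0, sqrt(gain / fan_in)),
               ly$cin, 4 * ly$cout)
    }
    params[[paste0(nm, ".b")]] <-
      rep(0, if (ly$kind == "conv") ly$cout else ly$cout)
  }
  params
}

n_parameters <- function(net) sum(vapply(net$params, length, numeric(1)))

#' Structure report of a built network
#'
#' @param network a `cs_network` from [build_network()].
#' @return data.frame with one row per encoder level (level 0 = input
#'   resolution) giving feature-map height, width and channel count;
#'   attributes `n_parameters` (total trainable parameter count),
#'   `n_outputs` (number of supervised outputs) and `supervision_weights`.
#' @export
summarize_network <- function(network) {
  spec <- network$spec
  L <- spec$depth
  lev <- 0:L
  rep <- data.frame(level = lev,
                    height = spec$input_height %/% 2L^lev,
                    width = spec$input_width %/% 2L^lev,
                    channels = vapply(lev, function(l) as.numeric(channels_at(spec, l)),
                                      numeric(1)))
  attr(rep, "n_parameters") <- n_parameters(network)
  attr(rep, "n_outputs") <- if (spec$use_deep_supervision) L + 1L else 1L
  attr(rep, "supervision_weights") <-
    if (spec$use_deep_supervision) spec$supervision_weights else 1
  attr(rep, "has_identity_paths") <- spec$use_residual
  rep
}
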