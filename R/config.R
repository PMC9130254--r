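# Pipeline configuration: a schema-versioned YAML/JSON file with one section
# per stage. Unknown sections or keys are rejected before any stage runs.

cs_config_schema <- function() {
  list(
    schema_version = NULL,
    canvas = c("height", "width", "target_voxel"),
    network = c("input_height", "input_width", "depth", "base_filters",
                "filters_double_per_level", "use_residual",
                "use_deep_supervision", "activation", "supervision_weights"),
    training = c("learning_rate", "amsgrad", "batch_size", "epochs",
                 "beta1", "beta2", "eps", "seed"),
    augmentation = c("enabled", "preset", "rotation_range", "gamma_range",
                     "scale_range", "elastic_spacing", "elastic_max_disp"),
    cv = c("k", "seed", "subsample", "background_stride", "foreground_stride"),
    inference = c("threshold", "save_probabilities"),
    thickness = c("bin_width_um"),
    phantom = c("preset", "n", "seed", "shell_thickness_range",
                "n_mutant", "n_poor_staining"))
}

#' Default pipeline configuration
#'
#' All sections at their published / package defaults; serializable to YAML
#' or JSON and accepted by [read_pipeline_config()].
#'
#' @param desk use the desk-scale canvas/network/phantom sizes instead of
#'   the full published scale.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(desk = FALSE) {
  cfg <- list(
    schema_version = 1L,
    canvas = list(height = 1792L, width = 1280L, target_voxel = 6),
    network = list(input_height = 1792L, input_width = 1280L, depth = 6L,
                   base_filters = 16L, filters_double_per_level = TRUE,
                   use_residual = TRUE, use_deep_supervision = TRUE,
                   activation = "SELU",
                   supervision_weights = default_supervision_weights(6L)),
    training = list(learning_rate = 1e-4, amsgrad = TRUE, batch_size = 4L,
                    epochs = 50L, seed = 1L),
    augmentation = list(enabled = TRUE, preset = "paper2022",
                        elastic_spacing = 128, elastic_max_disp = 10),
    cv = list(k = 7L, seed = 1L, subsample = FALSE,
              background_stride = 200L, foreground_stride = 30L),
    inference = list(threshold = 0.5, save_probabilities = FALSE),
    thickness = list(bin_width_um = 6),
    phantom = list(preset = "default", n = 14L, seed = 7L,
                   shell_thickness_range = c(24, 36)))
  if (desk) {
    cfg$canvas <- list(height = 64L, width = 64L, target_voxel = 6)
    cfg$network$input_height <- 64L
    cfg$network$input_width <- 64L
    cfg$network$depth <- 4L
    cfg$network$base_filters <- 8L
    cfg$network$supervision_weights <- default_supervision_weights(4L)
    cfg$training$epochs <- 12L
    cfg$augmentation$elastic_spacing <- 32
    cfg$augmentation$elastic_max_disp <- 4
    cfg$cv$subsample <- TRUE
    cfg$cv$background_stride <- 24L
    cfg$cv$foreground_stride <- 4L
    cfg$phantom$preset <- "desk"
  }
  cfg
}

validate_pipeline_config <- function(cfg) {
  schema <- cs_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    cs_config_error(sprintf("unknown config section(s): %s",
                            paste(unknown, collapse = ", ")))
  if (is.null(cfg$schema_version))
    cs_config_error("config is missing 'schema_version'")
  for (sec in setdiff(names(cfg), "schema_version")) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      cs_config_error(sprintf("unknown key(s) in section '%s': %s",
                              sec, paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read and validate a pipeline configuration file
#'
#' @param path a `.yaml`/`.yml` or `.json` file; sections absent from the
#'   file fall back to package defaults.
#' @param desk base defaults on the desk-scale configuration.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path, desk = FALSE) {
  if (!file.exists(path)) cs_config_error(sprintf("config not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_pipeline_config(raw)
  cfg <- modifyList(default_pipeline_config(desk = desk), raw)
  validate_pipeline_config(cfg)
  cfg
}

config_objects <- function(cfg) {
  canvas <- canvas_spec(cfg$canvas$height, cfg$canvas$width,
                        cfg$canvas$target_voxel)
  w <- cfg$network$supervision_weights
  # config serialization (YAML/JSON) rounds the weights; renormalize
  # rounding-level deviations, let real errors surface in network_spec()
  if (!is.null(w) && abs(sum(w) - 1) < 1e-4) w <- w / sum(w)
  spec <- network_spec(cfg$network$input_height, cfg$network$input_width,
                       cfg$network$depth, cfg$network$base_filters,
                       cfg$network$filters_double_per_level,
                       cfg$network$use_residual,
                       cfg$network$use_deep_supervision,
                       cfg$network$activation,
                       w)
  tc <- cfg$training
  config <- training_config(tc$learning_rate, tc$amsgrad, tc$batch_size,
                            tc$epochs,
                            tc$beta1 %||% 0.9, tc$beta2 %||% 0.999,
                            tc$eps %||% 1e-8, tc$seed)
  policy <- if (isTRUE(cfg$augmentation$enabled)) {
    au <- cfg$augmentation
    augmentation_policy(
      rotation_range = au$rotation_range %||% c(-10, 10),
      gamma_range = au$gamma_range %||% c(0.9, 1.1),
      scale_range = au$scale_range %||% c(0.9, 1.1),
      elastic_params = list(spacing = au$elastic_spacing %||% 128,
                            max_disp = au$elastic_max_disp %||% 10))
  } else NULL
  rule <- if (isTRUE(cfg$cv$subsample))
    subsample_rule(cfg$cv$background_stride, cfg$cv$foreground_stride)
  else NULL
  list(canvas = canvas, spec = spec, config = config, policy = policy,
       rule = rule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
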