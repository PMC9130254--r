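#' Training configuration
#'
#' Defaults reproduce the published setup: Adam with AMSgrad, initial
#' learning rate 1e-4, mini-batches of 4 slices, 50 epochs.
#'
#' @param learning_rate Adam step size.
#' @param amsgrad use the AMSgrad variant (maximum of past second moments).
#' @param batch_size slices per optimization step (gradients averaged).
#' @param epochs passes over the training slices.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed master seed for shuffling, augmentation and initialization.
#' @return a `cs_trainconfig` object.
#' @export
training_config <- function(learning_rate = 1e-4, amsgrad = TRUE,
                            batch_size = 4, epochs = 50,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            seed = 1L) {
  if (learning_rate <= 0) cs_config_error("learning_rate must be > 0")
  if (batch_size < 1) cs_config_error("batch_size must be >= 1")
  if (epochs < 0) cs_config_error("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, amsgrad = isTRUE(amsgrad),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "cs_trainconfig")
}

#' Plan a k-fold cross-validation
#'
#' Deterministic given the seed; validation sets are disjoint, exhaustive,
#' and differ in size by at most one sample.
#'
#' @param sample_ids character or integer vector of sample identifiers.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return a `cs_foldplan`: list with `assignments` (named fold index per
#'   sample) and `k`.
#' @export
make_folds <- function(sample_ids, k, seed = 1L) {
  n <- length(sample_ids)
  if (k > n) cs_config_error(sprintf("k = %d exceeds the %d samples", k, n))
  if (k < 2) cs_config_error("k must be >= 2")
  perm <- with_seed(seed, sample.int(n))
  fold <- rep(seq_len(k), length.out = n)[order(perm)]
  # rep assigns near-equal sizes; order(perm) scatters them over samples
  names(fold) <- as.character(sample_ids)
  structure(list(assignments = fold, k = as.integer(k)), class = "cs_foldplan")
}

#' Ablation slice-subsampling rule
#'
#' Within the contiguous axial index range whose slices contain foreground,
#' every `foreground_stride`-th slice is kept; outside it, every
#' `background_stride`-th slice. The published ablation uses every 30th
#' cartilage-region slice and every 200th cartilage-free slice.
#'
#' @param background_stride,foreground_stride strides, >= 1.
#' @return a `cs_subsample_rule`.
#' @export
subsample_rule <- function(background_stride = 200, foreground_stride = 30) {
  if (background_stride < 1 || foreground_stride < 1)
    cs_config_error("strides must be >= 1")
  structure(list(background_stride = as.integer(background_stride),
                 foreground_stride = as.integer(foreground_stride)),
            class = "cs_subsample_rule")
}

#' Select training slice indices under a subsampling rule
#'
#' @param mask a [cs_mask()].
#' @param rule a [subsample_rule()].
#' @return sorted, duplicate-free 1-based slice indices.
#' @export
subsample_slices <- function(mask, rule) {
  d <- dim(mask$data)
  has_fg <- vapply(seq_len(d[1]), function(k) any(mask$data[k, , ] != 0),
                   logical(1))
  idx <- integer(0)
  if (any(has_fg)) {
    lo <- min(which(has_fg))
    hi <- max(which(has_fg))
    idx <- c(idx, seq(lo, hi, by = rule$foreground_stride))
    if (lo > 1) idx <- c(idx, seq(1L, lo - 1L, by = rule$background_stride))
    if (hi < d[1]) idx <- c(idx, seq(hi + 1L, d[1], by = rule$background_stride))
  } else {
    idx <- seq(1L, d[1], by = rule$background_stride)
  }
  sort(unique(as.integer(idx)))
}

#' Preprocess a volume/mask pair into canvas-grid training slices
#'
#' Applies the canvas pipeline (in-plane rescale to the target voxel size,
#' centre pad/crop, whole-volume standardization) and extracts axial slices.
#'
#' @param vol a [cs_volume()].
#' @param mask the matching [cs_mask()].
#' @param canvas a [canvas_spec()].
#' @param rule optional [subsample_rule()]; default keeps every slice.
#' @return list of examples, each `list(image, mask)` of canvas-size matrices.
#' @export
prepare_training_slices <- function(vol, mask, canvas, rule = NULL) {
  rv <- rescale_voxels(vol, canvas$target_voxel)
  rm_ <- rescale_voxels(mask, canvas$target_voxel)
  fv <- fit_to_canvas(rv$volume, canvas, rv$transform)
  fm <- fit_to_canvas(rm_$volume, canvas, rm_$transform)
  sv <- standardize(fv$volume)
  keep <- if (is.null(rule)) seq_len(dim(sv$data)[1])
          else subsample_slices(fm$volume, rule)
  lapply(keep, function(k)
    list(image = sv$data[k, , ], mask = fm$volume$data[k, , ]))
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, vhat = zeros, t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1
  b2 <- cfg$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    vuse <- if (cfg$amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      state$vhat[[nm]]
    } else state$v[[nm]]
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / c1) / (sqrt(vuse / c2) + cfg$eps)
  }
  list(params = params, state = state)
}

# Composite loss + output gradients for one example.
example_loss_grads <- function(network, outputs, truth, smooth = 1e-6) {
  spec <- network$spec
  if (spec$use_deep_supervision) {
    w <- spec$supervision_weights
    nms <- names(outputs)
    gouts <- list()
    loss <- 0
    for (i in seq_along(nms)) {
      lg <- dice_loss_grad(outputs[[i]], truth, smooth)
      loss <- loss + w[i] * lg$loss
      gouts[[nms[i]]] <- w[i] * lg$grad
    }
    list(loss = loss, gouts = gouts)
  } else {
    lg <- dice_loss_grad(outputs$main, truth, smooth)
    list(loss = lg$loss, gouts = list(main = lg$grad))
  }
}

example_loss <- function(network, ex) {
  fw <- net_forward(network, ex$image, keep_cache = FALSE)
  example_loss_grads(network, fw$outputs, ex$mask)$loss
}

#' Train the network
#'
#' Minimizes the (deep-supervision weighted) Dice loss over shuffled
#' mini-batches with Adam/AMSgrad and on-the-fly augmentation, recording
#' per-epoch training and validation loss and returning the weights from the
#' epoch with the lowest validation loss (training loss when no validation
#' set is given). All stochastic sources — shuffling, augmentation — derive
#' from `config$seed`.
#'
#' @param network a `cs_network` from [build_network()].
#' @param train_examples list of `list(image, mask)` canvas slices, e.g.
#'   from [prepare_training_slices()].
#' @param config a [training_config()].
#' @param policy optional [augmentation_policy()] applied on the fly.
#' @param val_examples optional validation slices for best-epoch selection.
#' @return list with `network` (best weights), `history` (data.frame of
#'   epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_model <- function(network, train_examples, config,
                        policy = NULL, val_examples = NULL) {
  if (length(train_examples) == 0) cs_data_error("empty training set")
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(params = network$params, crit = Inf, epoch = 0L)
  if (config$epochs == 0L)
    return(list(network = network, history = hist, best_epoch = 0L))
  state <- adam_init(network$params)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(train_examples))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL
        bloss <- 0
        for (i in batch) {
          ex <- train_examples[[i]]
          if (!is.null(policy)) {
            aug <- augment_example(ex$image, ex$mask, policy)
            ex <- list(image = aug$image, mask = aug$mask)
          }
          fw <- net_forward(network, ex$image, keep_cache = TRUE)
          lg <- example_loss_grads(network, fw$outputs, ex$mask)
          bloss <- bloss + lg$loss
          gr <- net_backward(network, fw$cache, lg$gouts)
          acc <- if (is.null(acc)) gr
                 else { for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]; acc }
        }
        nb1 <- length(batch)
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb1
        st <- adam_step(network$params, acc, state, config)
        network$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + bloss / nb1
        nb <- nb + 1L
      }
      train_loss <- ep_loss / nb
      val_loss <- if (!is.null(val_examples))
        mean(vapply(val_examples, function(ex) example_loss(network, ex),
                    numeric(1))) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = train_loss,
                                     val_loss = val_loss))
      crit <- if (is.na(val_loss)) train_loss else val_loss
      if (crit < best$crit) best <- list(params = network$params, crit = crit,
                                         epoch = ep)
    }
  })
  network$params <- best$params
  list(network = network, history = hist, best_epoch = best$epoch)
}

#' Cross-validate the segmentation pipeline on a sample set
#'
#' For each fold of the plan, trains on the training samples' slices and
#' evaluates volume-level Dice on every validation sample through
#' [segment_volume()] on the native grid.
#'
#' @param samples named list; each element holds `volume` (a [cs_volume()])
#'   and `truth` (its [cs_mask()]).
#' @param plan a [make_folds()] plan over `names(samples)`.
#' @param spec a [network_spec()] (input size must match the canvas).
#' @param config a [training_config()].
#' @param canvas a [canvas_spec()].
#' @param policy optional [augmentation_policy()].
#' @param rule optional [subsample_rule()] for slice subsampling.
#' @return data.frame with one row per sample: `sample_id`, `fold`, `dice`.
#' @export
cross_validate <- function(samples, plan, spec, config, canvas,
                           policy = NULL, rule = NULL) {
  ids <- names(samples)
  if (is.null(ids) || !all(ids %in% names(plan$assignments)))
    cs_config_error("samples must be named and covered by the fold plan")
  rows <- list()
  for (f in seq_len(plan$k)) {
    val_ids <- ids[plan$assignments[ids] == f]
    tr_ids <- setdiff(ids, val_ids)
    tr_ex <- unlist(lapply(tr_ids, function(id)
      prepare_training_slices(samples[[id]]$volume, samples[[id]]$truth,
                              canvas, rule)), recursive = FALSE)
    net <- build_network(spec, seed = config$seed + f)
    fit <- train_model(net, tr_ex, config, policy = policy)
    for (id in val_ids) {
      seg <- segment_volume(samples[[id]]$volume, fit$network, canvas)
      rows[[id]] <- data.frame(sample_id = id, fold = f,
                               dice = dice_coefficient(seg$mask,
                                                       samples[[id]]$truth))
    }
  }
  out <- do.call(rbind, rows[ids])
  rownames(out) <- NULL
  out
}
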