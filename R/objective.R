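#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2*TP / (2*TP + FP + FN)`. Two empty
#' masks agree perfectly on absence and score 1.
#'
#' @param pred,truth binary arrays/matrices of identical shape (a
#'   [cs_mask()] may be passed for either).
#' @return a fraction in \[0, 1\], symmetric in its arguments.
#' @export
dice_coefficient <- function(pred, truth) {
  pred <- mask_data(pred)
  truth <- mask_data(truth)
  if (!identical(dim2(pred), dim2(truth)))
    cs_data_error(sprintf("shape mismatch: pred %s vs truth %s",
                          paste(dim2(pred), collapse = "x"),
                          paste(dim2(truth), collapse = "x")))
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

mask_data <- function(x) {
  if (inherits(x, "cs_mask") || inherits(x, "cs_volume")) x$data else x
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Confusion counts between two binary grids
#' @inheritParams dice_coefficient
#' @return list with `TP`, `TN`, `FP`, `FN` voxel counts.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- mask_data(pred)
  truth <- mask_data(truth)
  if (!identical(dim2(pred), dim2(truth)))
    cs_data_error("shape mismatch between pred and truth")
  list(TP = sum(pred == 1 & truth == 1), TN = sum(pred == 0 & truth == 0),
       FP = sum(pred == 1 & truth == 0), FN = sum(pred == 0 & truth == 1))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred*truth) + smooth) / (sum(pred) + sum(truth) + smooth)`,
#' differentiable in the predicted probabilities. With both inputs empty the
#' smoothing term makes the loss exactly 0.
#'
#' @param pred probability grid in \[0, 1\].
#' @param truth binary grid of the same shape.
#' @param smooth small additive smoothing constant.
#' @return scalar loss, >= 0.
#' @export
dice_loss <- function(pred, truth, smooth = 1e-6) {
  if (!identical(dim2(pred), dim2(truth)))
    cs_data_error("shape mismatch between pred and truth")
  num <- 2 * sum(pred * truth) + smooth
  den <- sum(pred) + sum(truth) + smooth
  1 - num / den
}

# Loss and analytic gradient w.r.t. pred, for the training loop.
dice_loss_grad <- function(pred, truth, smooth = 1e-6) {
  num <- 2 * sum(pred * truth) + smooth
  den <- sum(pred) + sum(truth) + smooth
  list(loss = 1 - num / den, grad = (num - 2 * truth * den) / den^2)
}

#' Deep-supervision composite loss
#'
#' Weighted sum of per-head Dice losses; every head prediction must already
#' be at ground-truth resolution. Weights are given deepest head first, the
#' largest weights belonging to the heads with the largest feature maps.
#'
#' @param head_preds list of probability grids (deepest first).
#' @param truth binary grid.
#' @param weights positive weights, one per head, summing to 1.
#' @param smooth smoothing constant passed to [dice_loss()].
#' @return scalar composite loss.
#' @export
deep_supervision_loss <- function(head_preds, truth, weights, smooth = 1e-6) {
  if (length(head_preds) != length(weights))
    cs_data_error(sprintf("%d heads but %d weights",
                          length(head_preds), length(weights)))
  sum(vapply(seq_along(head_preds),
             function(i) weights[i] * dice_loss(head_preds[[i]], truth, smooth),
             numeric(1)))
}
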