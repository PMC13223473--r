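# Compound segmentation loss (weighted BCE + soft Dice + soft IoU) and the
# voxel-overlap evaluation metrics. The plain-array functions below consume
# sigmoid probabilities; the trainer uses the fused logits version
# `seg_loss_with_grad()` for numerical stability.

#' Loss weight configuration
#'
#' The three component weights must lie on the probability simplex
#' (`w_bce + w_dice + w_iou == 1`); `alpha` up-weights positive (nodule)
#' voxels inside the BCE term to counter the extreme class imbalance of
#' nodule patches, and `epsilon` is the smoothing constant of the soft Dice
#' and IoU ratios. The defaults are the swarm-optimized operating point
#' (BCE 0.2093, Dice 0.4702, IoU 0.3205, alpha 1.56).
#'
#' @param w_bce,w_dice,w_iou nonnegative component weights summing to 1.
#' @param alpha positive-class weight of the BCE term (> 0).
#' @param epsilon smoothing constant (> 0).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(w_bce = 0.2093, w_dice = 0.4702, w_iou = 0.3205,
                         alpha = 1.56, epsilon = 1e-5) {
  if (any(c(w_bce, w_dice, w_iou) < 0) ||
      abs(w_bce + w_dice + w_iou - 1) > 1e-6) {
    stop("loss_weights: (w_bce, w_dice, w_iou) must be nonnegative and sum ",
         "to 1 (got sum = ", w_bce + w_dice + w_iou, ")")
  }
  if (alpha <= 0) stop("loss_weights: alpha must be positive")
  if (epsilon <= 0) stop("loss_weights: epsilon must be positive")
  structure(list(w_bce = w_bce, w_dice = w_dice, w_iou = w_iou,
                 alpha = alpha, epsilon = epsilon),
            class = "loss_weights")
}

clamp_prob <- function(prob) {
  if (any(prob <= 0 | prob >= 1)) {
    warning("probabilities outside (0, 1); clamping to [1e-7, 1 - 1e-7]")
    prob <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  }
  prob
}

#' Class-weighted binary cross-entropy
#'
#' Mean over voxels of `-(alpha * y * log(p) + (1 - y) * log(1 - p))`.
#'
#' @param prob predicted probabilities in (0, 1); values outside are clamped
#'   with a warning.
#' @param target binary ground-truth array of the same shape.
#' @param alpha positive-class weight.
#' @return scalar loss (>= 0).
#' @export
weighted_bce <- function(prob, target, alpha = 1.56) {
  stopifnot(length(prob) == length(target))
  prob <- clamp_prob(prob)
  -mean(alpha * target * log(prob) + (1 - target) * log(1 - prob))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)`. The smoothing
#' constant makes the empty/empty case a perfect score.
#'
#' @inheritParams weighted_bce
#' @param epsilon smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(prob, target, epsilon = 1e-5) {
  stopifnot(length(prob) == length(target))
  inter <- sum(prob * target)
  1 - (2 * inter + epsilon) / (sum(prob) + sum(target) + epsilon)
}

#' Soft IoU (Jaccard) loss
#'
#' `1 - (I + eps) / (U + eps)` with `U = sum(p) + sum(y) - I`, so overlap is
#' not double counted.
#'
#' @inheritParams dice_loss
#' @return scalar in `[0, 1]`.
#' @export
iou_loss <- function(prob, target, epsilon = 1e-5) {
  stopifnot(length(prob) == length(target))
  inter <- sum(prob * target)
  union <- sum(prob) + sum(target) - inter
  1 - (inter + epsilon) / (union + epsilon)
}

#' Compound segmentation loss
#'
#' `w_bce * L_BCE + w_dice * L_Dice + w_iou * L_IoU` with the weights of a
#' [loss_weights()] object.
#'
#' @inheritParams weighted_bce
#' @param lw a [loss_weights()] configuration.
#' @return scalar loss.
#' @export
combined_loss <- function(prob, target, lw = loss_weights()) {
  if (!inherits(lw, "loss_weights")) lw <- do.call(loss_weights, as.list(lw))
  lw$w_bce * weighted_bce(prob, target, lw$alpha) +
    lw$w_dice * dice_loss(prob, target, lw$epsilon) +
    lw$w_iou * iou_loss(prob, target, lw$epsilon)
}

# fused loss on logits with analytic gradient; returns list(loss, grad,
# parts). softplus is evaluated in its overflow-safe form.
seg_loss_with_grad <- function(logits, target, lw = loss_weights()) {
  z <- as.vector(logits); y <- as.vector(target)
  n <- length(z)
  p <- stats::plogis(z)
  sp_pos <- pmax(z, 0) + log1p(exp(-abs(z)))   # softplus(z)
  sp_neg <- sp_pos - z                          # softplus(-z)
  l_bce <- mean(lw$alpha * y * sp_neg + (1 - y) * sp_pos)
  g_bce <- (lw$alpha * y * (p - 1) + (1 - y) * p) / n

  eps <- lw$epsilon
  inter <- sum(p * y); sp <- sum(p); sy <- sum(y)
  denom_d <- sp + sy + eps
  l_dice <- 1 - (2 * inter + eps) / denom_d
  gp_dice <- -(2 * y * denom_d - (2 * inter + eps)) / denom_d^2

  uni <- sp + sy - inter
  denom_i <- uni + eps
  l_iou <- 1 - (inter + eps) / denom_i
  gp_iou <- -(y * denom_i - (inter + eps) * (1 - y)) / denom_i^2

  dpdz <- p * (1 - p)
  grad <- lw$w_bce * g_bce + (lw$w_dice * gp_dice + lw$w_iou * gp_iou) * dpdz
  dim(grad) <- dim(logits)
  list(loss = lw$w_bce * l_bce + lw$w_dice * l_dice + lw$w_iou * l_iou,
       grad = grad,
       parts = c(bce = l_bce, dice = l_dice, iou = l_iou))
}

# autograd wrapper used by the trainer
ag_seg_loss <- function(logits, target, lw = loss_weights()) {
  res <- seg_loss_with_grad(ag_value(logits), target, lw)
  ag_op(res$loss, list(logits), function(g) list(g * res$grad))
}

#' Voxel-overlap segmentation metrics
#'
#' Dice similarity coefficient, sensitivity and positive predictive value of
#' a hard (binary) prediction against a binary reference. Degenerate cases
#' follow fixed conventions needed for patches with empty reference masks:
#' with no reference positives, sensitivity is 1 when there are no false
#' positives and 0 otherwise (symmetrically for PPV with no predicted
#' positives), and Dice is 1 when both masks are empty.
#'
#' @param pred binary predicted mask (threshold 0.5 applied upstream).
#' @param target binary reference mask of the same shape.
#' @return named numeric vector `c(dsc, sen, ppv)`, each in `[0, 1]`.
#' @export
segmentation_metrics <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  p <- as.logical(pred); y <- as.logical(target)
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
  dsc <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  sen <- if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn)
  ppv <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  c(dsc = dsc, sen = sen, ppv = ppv)
}

#' Confusion counts at a threshold
#' @param prob probability or score array.
#' @param target binary reference mask.
#' @param threshold decision threshold (default 0.5).
#' @return named vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(prob, target, threshold = 0.5) {
  p <- as.vector(prob) >= threshold; y <- as.vector(target) > 0
  c(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y), TN = sum(!p & !y))
}
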