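#' Dice similarity coefficient between two binary masks
#'
#' Computes `(2 |P ∩ R| + eps) / (|P| + |R| + eps)` where `P` is the predicted
#' and `R` the reference (ground-truth) mask.  With `smooth = 0` and both
#' masks empty the score is 1 by convention: perfect agreement on the absence
#' of a lesion.
#'
#' @param pred,truth binary masks (0/1) of identical shape.
#' @param smooth smoothing constant added to numerator and denominator
#'   (default 0; use a positive value inside losses for stability).
#' @return a scalar in \[0, 1\].
#' @seealso [iou()] for the Jaccard index; the two are related by
#'   `D = 2J / (1 + J)`.
#' @export
dice_coefficient <- function(pred, truth, smooth = 0) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop_param("`pred` and `truth` must have identical shapes")
  }
  check_number(smooth, "smooth", lower = 0)
  inter <- sum(pred * truth)
  denom <- sum(pred) + sum(truth)
  if (denom + smooth == 0) return(1)
  (2 * inter + smooth) / (denom + smooth)
}

#' Intersection-over-union (Jaccard index) between two binary masks
#'
#' @inheritParams dice_coefficient
#' @return a scalar in \[0, 1\]; both masks empty gives 1 by convention.
#' @export
iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop_param("`pred` and `truth` must have identical shapes")
  }
  inter <- sum(pred * truth)
  un <- sum(pred) + sum(truth) - inter
  if (un == 0) return(1)
  inter / un
}

#' Soft dice loss
#'
#' `1 - soft dice`, where the soft dice is computed on probabilities rather
#' than thresholded masks, per sample, then averaged over the batch (the
#' fourth array dimension, when present).
#'
#' @param pred_probs predicted foreground probabilities in \[0, 1\], either a
#'   single mask or a 4-d array `(H, W, C, N)`.
#' @param truth ground-truth binary mask(s), same shape.
#' @param smooth smoothing constant (default 1, the usual training setting).
#' @return a scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred_probs, truth, smooth = 1) {
  if (length(dim(pred_probs)) == 4L) {
    n <- dim(pred_probs)[4]
    losses <- vapply(seq_len(n), function(i) {
      1 - soft_dice(pred_probs[, , , i], truth[, , , i], smooth)
    }, numeric(1))
    mean(losses)
  } else {
    1 - soft_dice(pred_probs, truth, smooth)
  }
}

soft_dice <- function(p, t, smooth) {
  denom <- sum(p) + sum(t) + smooth
  if (denom == 0) return(1)
  (2 * sum(p * t) + smooth) / denom
}

# Gradient of the per-sample soft-dice *loss* with respect to pred_probs.
dice_loss_grad <- function(p, t, smooth) {
  s <- sum(p) + sum(t) + smooth
  num <- 2 * sum(p * t) + smooth
  -(2 * t * s - num) / (s * s)
}

#' Focal loss for classification
#'
#' The canonical focal loss `-alpha * (1 - p_t)^gamma * log(p_t)` averaged
#' over the batch, where `p_t` is the predicted probability of the true
#' class.  `gamma = 0, alpha = 1` reduces to cross-entropy.
#'
#' @param class_probs matrix of class probabilities, one row per sample
#'   (rows sum to 1), or a single probability vector.
#' @param true_label integer class indices (1-based), one per sample.
#' @param gamma focusing exponent, >= 0 (default 2).
#' @param alpha balancing weight in (0, 1\] (default 0.25).
#' @param eps clamp on `p_t` to avoid `log(0)`.
#' @return a scalar loss, >= 0.
#' @export
focal_loss <- function(class_probs, true_label, gamma = 2, alpha = 0.25,
                       eps = 1e-12) {
  check_number(gamma, "gamma", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (is.null(dim(class_probs))) {
    class_probs <- matrix(class_probs, nrow = 1)
  }
  stopifnot(nrow(class_probs) == length(true_label))
  pt <- class_probs[cbind(seq_len(nrow(class_probs)), as.integer(true_label))]
  pt <- pmin(pmax(pt, eps), 1)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Loss configuration for the multi-task objective
#'
#' @param balance_delta weight `delta` on the segmentation (dice) term in the
#'   total loss `M = M_focal + delta * M_dice` (default 1).
#' @param focal_gamma,focal_alpha focal-loss parameters (defaults 2, 0.25).
#' @param smooth dice smoothing used in the loss (default 1; the reported
#'   dice metric always uses 0).
#' @return a `loss_config` list.
#' @export
loss_config <- function(balance_delta = 1, focal_gamma = 2,
                        focal_alpha = 0.25, smooth = 1) {
  check_number(balance_delta, "balance_delta", lower = 0)
  check_number(focal_gamma, "focal_gamma", lower = 0)
  check_number(focal_alpha, "focal_alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(smooth, "smooth", lower = 0)
  structure(list(balance_delta = balance_delta, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, smooth = smooth),
            class = "loss_config")
}

#' Multi-task loss: focal classification + weighted dice segmentation
#'
#' `M = M_focal(class) + delta * M_dice(segmentation)`.
#'
#' @param seg_out predicted segmentation probabilities `(H, W, 1, N)`.
#' @param seg_truth binary ground-truth masks, same shape.
#' @param class_out class-probability matrix, one row per sample.
#' @param class_truth integer true class indices (1-based).
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
multitask_loss <- function(seg_out, seg_truth, class_out, class_truth,
                           cfg = loss_config()) {
  fl <- focal_loss(class_out, class_truth, gamma = cfg$focal_gamma,
                   alpha = cfg$focal_alpha)
  dl <- dice_loss(seg_out, seg_truth, smooth = cfg$smooth)
  fl + cfg$balance_delta * dl
}

#' Confusion-matrix classification metrics
#'
#' Computes accuracy, precision, sensitivity (recall), specificity, and F1
#' from true/false positive/negative counts.  Ratios with a zero denominator
#' are returned as `NaN` with a warning rather than silently coerced to 0.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return a list with elements `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, and the counts.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn)) check_number(v, "count", lower = 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning NaN", what),
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = ratio(tp + tn, tp + fp + tn + fn, "accuracy"),
    precision = ratio(tp, tp + fp, "precision"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    f1 = ratio(2 * tp, 2 * tp + fp + fn, "F1")
  )
}

#' ROC curve and area under it
#'
#' Sweeps all distinct score thresholds, returning the (FPR, TPR) points and
#' the trapezoidal AUC.  With ties handled by the trapezoid over distinct
#' scores, the AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative (ties counting one half).
#'
#' @param scores positive-class probabilities or arbitrary decision scores.
#' @param labels 0/1 (or logical) labels; 1 = positive.
#' @return a list with `roc` (data.frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop_param("`scores` and `labels` must have equal length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_param("AUC undefined: need at least one positive and one negative")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
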