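# Seeded training loop: Adam on the multi-task dice+focal objective, with
# plateau learning-rate decay and best-checkpoint selection on validation
# dice.

CLASS_LEVELS <- c("SDH", "EDH")

#' Training configuration
#'
#' Defaults follow the published training recipe: learning rate 1e-4 decayed
#' by 0.5 on plateau, 60 epochs, batch size 16, Adam, dice segmentation loss
#' (plus the focal classification term of the multi-task objective).
#'
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param lr_decay_factor multiplicative decay on plateau, in (0, 1)
#'   (default 0.5).
#' @param lr_patience epochs without validation-loss improvement before the
#'   decay triggers (default 10).
#' @param epochs training epochs, >= 1 (default 60).
#' @param batch_size samples per batch (default 16).
#' @param val_fraction fraction of the training set carved out (stratified,
#'   seeded) for checkpoint selection when no validation set is supplied
#'   (default 0.1; 0 selects on training dice instead).
#' @param loss a [loss_config()] for the multi-task objective.
#' @param early_stop_dice optional target: stop as soon as the epoch's
#'   training dice reaches this value (default `NULL`, run all epochs).
#' @param seed integer seed for shuffling and the validation carve-out.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, lr_decay_factor = 0.5,
                         lr_patience = 10, epochs = 60, batch_size = 16,
                         val_fraction = 0.1, loss = loss_config(),
                         early_stop_dice = NULL, seed = NULL) {
  check_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_number(lr_decay_factor, "lr_decay_factor", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (lr_decay_factor >= 1) stop_param("`lr_decay_factor` must be < 1")
  check_number(epochs, "epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  check_number(lr_patience, "lr_patience", lower = 1)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, loss = loss,
                 early_stop_dice = early_stop_dice, seed = seed),
            class = "train_config")
}

manifest_to_arrays <- function(manifest) {
  recs <- manifest$records
  if (length(recs) == 0) stop_param("empty dataset")
  d <- dim(recs[[1]]$image)
  n <- length(recs)
  X <- array(0, c(d[1], d[2], 1L, n))
  M <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    X[, , 1L, i] <- recs[[i]]$image
    if (!is.null(recs[[i]]$mask)) M[, , 1L, i] <- recs[[i]]$mask
  }
  y <- match(vapply(recs, `[[`, character(1), "label"), CLASS_LEVELS)
  list(X = X, M = M, y = y)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(p)) {
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (k in keys) {
      if (is.null(g[[k]])) next
      r <- adam_step(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, beta1, beta2, eps)
      p[[k]] <- r$p
      m[[k]] <- r$m
      v[[k]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# gradient of the batch-mean focal loss w.r.t. the classifier logits
focal_grad_logits <- function(probs, labels, gamma, alpha, eps = 1e-12) {
  n <- nrow(probs)
  pt <- pmin(pmax(probs[cbind(seq_len(n), labels)], eps), 1 - 1e-12)
  term <- if (gamma == 0) 0 else alpha * gamma * (1 - pt)^(gamma - 1) * log(pt)
  dlpt <- term - alpha * (1 - pt)^gamma / pt
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), labels)] <- 1
  dz <- (onehot - probs) * pt * dlpt   # dp_t/dz_j = p_t (delta_tj - p_j)
  dz / n
}

batch_losses <- function(out, Mb, yb, loss_cfg) {
  dl <- dice_loss(out$seg_probs, Mb, smooth = loss_cfg$smooth)
  fl <- focal_loss(out$class_probs, yb, gamma = loss_cfg$focal_gamma,
                   alpha = loss_cfg$focal_alpha)
  list(total = fl + loss_cfg$balance_delta * dl, dice = dl, focal = fl)
}

#' Train a CSR-Unet on a labeled, preprocessed dataset
#'
#' Runs the standard loop: seeded shuffling each epoch, forward pass,
#' multi-task dice+focal loss, backprop, Adam update; after each epoch the
#' validation dice and loss are computed in evaluation mode, the learning
#' rate is halved after `lr_patience` stagnant epochs, and the checkpoint
#' with the best validation dice is retained.
#'
#' @param model a `csr_unet` from [build_model()].
#' @param train_set a `dataset_manifest` of preprocessed records (all images
#'   the same, /16-divisible size, with masks and labels).
#' @param val_set optional validation manifest; when `NULL` and
#'   `cfg$val_fraction > 0`, a stratified slice of `train_set` is held out.
#' @param cfg a [train_config()].
#' @param verbose print a line per epoch.
#' @return a list with `model` (the best checkpoint), `history` (per-epoch
#'   data.frame: losses, dice, learning rate), and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        cfg = train_config(), verbose = FALSE) {
  if (length(train_set$records) == 0) stop_param("empty training set")
  if (is.null(val_set) && cfg$val_fraction > 0 &&
      all(table(vapply(train_set$records, `[[`, character(1), "label")) >= 2)) {
    sp <- stratified_split(train_set, test_fraction = cfg$val_fraction,
                           seed = derive_seed(cfg$seed %||% 0L, "val"))
    if (length(sp$test$records) > 0) {
      train_set <- sp$train
      val_set <- sp$test
    }
  }
  tr <- manifest_to_arrays(train_set)
  va <- if (!is.null(val_set) && length(val_set$records) > 0) {
    manifest_to_arrays(val_set)
  } else {
    NULL
  }
  n <- dim(tr$X)[4]
  lr <- cfg$learning_rate
  mstate <- zeros_like(model$params)
  vstate <- zeros_like(model$params)
  t_step <- 0L
  history <- data.frame()
  best <- list(metric = -Inf, model = model, epoch = 0L)
  stagnant <- 0L
  best_val_loss <- Inf

  with_seed(cfg$seed, for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    ep_dice <- 0
    nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      Xb <- tr$X[, , , idx, drop = FALSE]
      Mb <- tr$M[, , , idx, drop = FALSE]
      yb <- tr$y[idx]
      out <- model_forward(model, Xb, training = TRUE)
      model$state <- out$state
      ls <- batch_losses(out, Mb, yb, cfg$loss)
      if (!is.finite(ls$total)) {
        stop_param(sprintf("non-finite loss at epoch %d (loss=%g)", epoch,
                           ls$total))
      }
      # gradients of the two heads
      nb_samples <- length(idx)
      dp <- array(0, dim(out$seg_probs))
      for (i in seq_len(nb_samples)) {
        dp[, , , i] <- dice_loss_grad(out$seg_probs[, , , i], Mb[, , , i],
                                      cfg$loss$smooth) / nb_samples
      }
      dz_seg <- cfg$loss$balance_delta * dp * out$seg_probs *
        (1 - out$seg_probs)
      dz_cls <- focal_grad_logits(out$class_probs, yb, cfg$loss$focal_gamma,
                                  cfg$loss$focal_alpha)
      bw <- model_backward(model, out$caches, dz_seg, dz_cls)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, bw$grads, mstate, vstate, lr, t_step)
      model$params <- upd$p
      mstate <- upd$m
      vstate <- upd$v
      ep_loss <- ep_loss + ls$total
      ep_dice <- ep_dice + mean(vapply(seq_len(nb_samples), function(i) {
        dice_coefficient((out$seg_probs[, , , i] >= 0.5) * 1, Mb[, , , i])
      }, numeric(1)))
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    ep_dice <- ep_dice / nb

    if (!is.null(va)) {
      vm <- eval_arrays(model, va, cfg$loss)
      val_loss <- vm$loss
      val_dice <- vm$dice
    } else {
      val_loss <- ep_loss
      val_dice <- ep_dice
    }
    metric <- val_dice
    if (metric > best$metric) {
      best <- list(metric = metric, model = model, epoch = epoch)
    }
    if (val_loss < best_val_loss - 1e-6) {
      best_val_loss <- val_loss
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= cfg$lr_patience) {
        lr <- lr * cfg$lr_decay_factor
        stagnant <- 0L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss, train_dice = ep_dice,
      val_loss = val_loss, val_dice = val_dice, lr = lr))
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  dice %.4f  val_loss %.4f  val_dice %.4f  lr %g",
        epoch, ep_loss, ep_dice, val_loss, val_dice, lr))
    }
    if (!is.null(cfg$early_stop_dice) && ep_dice >= cfg$early_stop_dice) {
      break
    }
  })
  list(model = best$model, history = history, best_epoch = best$epoch)
}

# loss + hard dice over a whole array set, evaluation mode, chunked
eval_arrays <- function(model, arrs, loss_cfg, chunk = 16L) {
  n <- dim(arrs$X)[4]
  loss <- 0
  dice <- 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out <- model_forward(model, arrs$X[, , , idx, drop = FALSE],
                         training = FALSE)
    Mb <- arrs$M[, , , idx, drop = FALSE]
    ls <- batch_losses(out, Mb, arrs$y[idx], loss_cfg)
    loss <- loss + ls$total * length(idx)
    dice <- dice + sum(vapply(seq_along(idx), function(i) {
      dice_coefficient((out$seg_probs[, , , i] >= 0.5) * 1, Mb[, , , i])
    }, numeric(1)))
  }
  list(loss = loss / n, dice = dice / n)
}

#' Evaluate a trained model on a test set
#'
#' Computes per-class and mean dice/IoU of the thresholded segmentation
#' masks, the classification confusion matrix with accuracy, precision,
#' sensitivity, specificity and F1 (positive class SDH), and the ROC curve
#' and AUC on the SDH probability.
#'
#' @param model a trained `csr_unet`.
#' @param test_set a `dataset_manifest` of resized+normalized records.
#' @param threshold segmentation probability threshold (default 0.5).
#' @return a `metrics_report` list.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5) {
  if (length(test_set$records) == 0) stop_param("empty test set")
  arrs <- manifest_to_arrays(test_set)
  n <- dim(arrs$X)[4]
  dices <- numeric(n)
  ious <- numeric(n)
  probs <- matrix(0, n, model$cfg$num_classes)
  for (start in seq(1, n, by = 16L)) {
    idx <- start:min(start + 15, n)
    out <- model_forward(model, arrs$X[, , , idx, drop = FALSE],
                         training = FALSE)
    for (j in seq_along(idx)) {
      i <- idx[j]
      pm <- (out$seg_probs[, , , j] >= threshold) * 1
      dices[i] <- dice_coefficient(pm, arrs$M[, , , i])
      ious[i] <- iou(pm, arrs$M[, , , i])
    }
    probs[idx, ] <- out$class_probs
  }
  labels <- CLASS_LEVELS[arrs$y]
  pred <- CLASS_LEVELS[max.col(probs, ties.method = "first")]
  per_class <- do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
    sel <- labels == cl
    data.frame(class = cl, n = sum(sel),
               dice = if (any(sel)) mean(dices[sel]) else NA_real_,
               iou = if (any(sel)) mean(ious[sel]) else NA_real_)
  }))
  pos <- "SDH"
  tp <- sum(pred == pos & labels == pos)
  fp <- sum(pred == pos & labels != pos)
  tn <- sum(pred != pos & labels != pos)
  fn <- sum(pred != pos & labels == pos)
  cls <- suppressWarnings(classification_metrics(tp, fp, tn, fn))
  roc <- if (length(unique(labels)) == 2L) {
    roc_auc(probs[, 1], labels == pos)
  } else {
    NULL
  }
  structure(list(
    n = n, per_class = per_class, mean_dice = mean(dices),
    mean_iou = mean(ious), dice_per_sample = dices, iou_per_sample = ious,
    confusion = cls[c("tp", "fp", "tn", "fn")],
    accuracy = cls$accuracy, precision = cls$precision,
    sensitivity = cls$sensitivity, specificity = cls$specificity,
    f1 = cls$f1, roc = roc$roc, auc = if (is.null(roc)) NA_real_ else roc$auc,
    positive_class = pos, class_probs = probs, pred_class = pred,
    true_class = labels), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  mean dice %.3f | mean IoU %.3f\n", x$mean_dice, x$mean_iou))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %s (n=%d): dice %.3f, IoU %.3f\n", x$per_class$class[i],
                x$per_class$n[i], x$per_class$dice[i], x$per_class$iou[i]))
  }
  cat(sprintf(
    "  classification: acc %.3f, prec %.3f, sens %.3f, spec %.3f, F1 %.3f, AUC %s\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$f1,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the configuration, weights and batch-norm state;
#' loading restores a model whose evaluation-mode outputs are identical.
#'
#' @param model a `csr_unet`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "csr_unet"))
  model
}
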