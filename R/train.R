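#' Training configuration
#'
#' Defaults mirror the study protocol: 5 folds, batch size 4, up to 100
#' epochs, Adam at learning rate 1e-4, a reduce-on-plateau schedule that
#' multiplies the learning rate by `learning_factor` = 0.2 whenever the
#' validation loss fails to improve for `epoch_patience` = 7 epochs, and
#' the SoftM_MSE loss (mean squared error between the softmax probabilities
#' and the one-hot target).
#'
#' @param n_folds,batch_size,n_epochs,epoch_patience positive integers.
#' @param learning_rate positive Adam step size.
#' @param learning_factor plateau multiplier in (0, 1).
#' @param val_fraction fraction of training segments moved to validation.
#' @param loss loss name; only `"SoftM_MSE"` is provided.
#' @param optimizer optimizer name; only `"Adam"` is provided.
#' @param seed integer controlling every random choice in training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_folds = 5L, batch_size = 4L, n_epochs = 100L,
                         learning_rate = 1e-4, epoch_patience = 7L,
                         learning_factor = 0.2, val_fraction = 0.10,
                         loss = "SoftM_MSE", optimizer = "Adam", seed = 1L) {
  cfg <- list(n_folds = as.integer(n_folds), batch_size = as.integer(batch_size),
              n_epochs = as.integer(n_epochs), learning_rate = learning_rate,
              epoch_patience = as.integer(epoch_patience),
              learning_factor = learning_factor, val_fraction = val_fraction,
              loss = loss, optimizer = optimizer, seed = as.integer(seed))
  if (cfg$n_folds < 1L || cfg$batch_size < 1L || cfg$n_epochs < 1L ||
      cfg$epoch_patience < 1L) stop("counts must be positive")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$learning_factor <= 0 || cfg$learning_factor >= 1)
    stop("learning_factor must lie in (0, 1)")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must lie in (0, 1)")
  if (!identical(cfg$loss, "SoftM_MSE")) stop("unsupported loss: ", loss)
  if (!identical(cfg$optimizer, "Adam")) stop("unsupported optimizer: ", optimizer)
  structure(cfg, class = "train_config")
}

#' SoftM_MSE loss
#'
#' Mean squared error between the softmax probabilities (the exponential of
#' the log-softmax network output) and the one-hot target, averaged over
#' classes and samples.  For two classes the loss lies in `[0, 1]` and is
#' zero exactly when every prediction is the correct one-hot vector.
#'
#' @param log_probs numeric vector (one sample) or matrix with classes in
#'   rows and samples in columns; each column must exponentiate to a
#'   probability vector (sum 1).
#' @param target_class integer class indices, 0-based, one per sample.
#' @return Non-negative scalar loss.
#' @examples
#' softm_mse_loss(log(c(0.5, 0.5)), 0)  # 0.25
#' @export
softm_mse_loss <- function(log_probs, target_class) {
  if (is.null(dim(log_probs))) log_probs <- matrix(log_probs, ncol = 1L)
  p <- exp(log_probs)
  if (any(abs(colSums(p) - 1) > 1e-6))
    stop("log_probs must be normalized log-probabilities (exp sums to 1)")
  C <- nrow(p); B <- ncol(p)
  target_class <- as.integer(target_class)
  if (length(target_class) != B) stop("one target class per sample required")
  if (any(target_class < 0L | target_class >= C)) stop("target class out of range")
  t <- matrix(0, C, B)
  t[cbind(target_class + 1L, seq_len(B))] <- 1
  mean((p - t)^2)
}

# Gradient of the SoftM_MSE loss w.r.t. the log-softmax outputs.  Because
# log_probs are already normalized, dL/dlp = dL/dp * p elementwise; the
# log-softmax layer's own backward handles the normalization coupling.
softm_mse_grad <- function(log_probs, target_class) {
  p <- exp(log_probs)
  C <- nrow(p); B <- ncol(p)
  t <- matrix(0, C, B)
  t[cbind(as.integer(target_class) + 1L, seq_len(B))] <- 1
  (2 / (C * B)) * (p - t) * p
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

# Class-stratified validation split: within every class, whole sessions are
# moved to validation until ~val_fraction of that class's segments is
# covered, so the validation set is session-independent AND contains both
# classes (model selection on a single-class validation set would reward a
# degenerate constant predictor).  Falls back to a stratified segment split
# for classes with a single training session.
split_validation <- function(sessions, labels, val_fraction) {
  idx_all <- integer(0)
  for (cl in sort(unique(labels))) {
    in_cl <- which(labels == cl)
    uniq <- unique(sessions[in_cl])
    take <- character(0)
    if (length(uniq) >= 2L) {
      ord <- sample(uniq)
      target <- val_fraction * length(in_cl)
      cum <- 0L
      for (s in ord) {
        ns <- sum(sessions[in_cl] == s)
        if (length(take) > 0L && cum + ns > 1.8 * target) next
        take <- c(take, s); cum <- cum + ns
        if (cum >= target) break
      }
      if (length(take) >= length(uniq))  # keep at least one training session
        take <- take[-length(take)]
    }
    idx_all <- c(idx_all,
                 if (length(take) > 0L) in_cl[sessions[in_cl] %in% take]
                 else sample(in_cl, max(1L, round(val_fraction * length(in_cl)))))
  }
  sort(idx_all)
}

#' Train a network on one cross-validation fold
#'
#' Runs the full training loop: a 10% validation split grouped by session
#' where the session count permits, per-segment standardization by the
#' training-set mean and standard deviation, Adam updates on mini-batches,
#' the reduce-on-plateau learning-rate schedule, and restoration of the
#' weights with the best validation loss.  Fully deterministic given
#' `config$seed`.
#'
#' @param network a `selfonn_net` from [build_self_resnet18()] or
#'   [build_self_resattentionet18()].
#' @param segments numeric matrix, one fixed-length segment per row.
#' @param labels integer class labels (0-based), one per segment.
#' @param sessions character session ids, one per segment (drives the
#'   grouped validation split).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return An object of class `selfonn_fit`: the trained network, the
#'   input standardization constants, and a `history` data frame with
#'   per-epoch train/validation loss and accuracy, the learning-rate trace
#'   and the best epoch.
#' @export
train_fold <- function(network, segments, labels, sessions = NULL,
                       config = train_config(), verbose = FALSE) {
  stopifnot(inherits(network, "selfonn_net"), inherits(config, "train_config"))
  if (!is.matrix(segments) || nrow(segments) < 2L)
    stop("segments must be a matrix with at least two rows")
  if (anyNA(segments)) stop("segments must be NaN-free (rejected segments are excluded upstream)")
  n <- nrow(segments)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per segment required")
  if (is.null(sessions)) sessions <- rep("all", n)
  set.seed(config$seed)

  vidx <- split_validation(sessions, labels, config$val_fraction)
  tidx <- setdiff(seq_len(n), vidx)
  if (length(tidx) == 0L || length(vidx) == 0L) stop("empty train or validation split")

  mu <- mean(segments[tidx, ])
  sdv <- sd(as.numeric(segments[tidx, ]))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xtr <- (segments[tidx, , drop = FALSE] - mu) / sdv
  xva <- (segments[vidx, , drop = FALSE] - mu) / sdv
  ytr <- labels[tidx]; yva <- labels[vidx]

  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  handle <- cpp_net_create(unclass(network$arch))
  lr <- config$learning_rate
  best_val <- Inf; best_epoch <- 0L
  best_params <- network$params
  best_buffers <- as.list(network$buffers)
  since_improve <- 0L
  hist <- list()

  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample(length(ytr))
    tr_loss <- 0; tr_correct <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- array(t(xtr[idx, , drop = FALSE]), dim = c(1L, ncol(xtr), length(idx)))
      res <- cpp_net_fwdbwd_h(handle, network$params, network$buffers,
                              xb, ytr[idx])
      network$params <- adam_step(network$params, res$grads, state, lr)
      tr_loss <- tr_loss + res$loss * length(idx)
      tr_correct <- tr_correct + sum(max.col(t(res$logp), ties.method = "first") - 1L == ytr[idx])
    }
    ev <- eval_loss_acc(network, xva, yva, config$batch_size * 8L, handle)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = tr_loss / length(ytr),
                                train_acc = tr_correct / length(ytr),
                                val_loss = ev$loss, val_acc = ev$acc, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %.2e",
                      epoch, tr_loss / length(ytr), tr_correct / length(ytr),
                      ev$loss, ev$acc, lr))
    if (ev$loss < best_val - 1e-8) {
      best_val <- ev$loss; best_epoch <- epoch
      best_params <- network$params
      best_buffers <- as.list(network$buffers)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$epoch_patience) {
        lr <- lr * config$learning_factor
        since_improve <- 0L
      }
    }
  }
  network$params <- best_params
  list2env(best_buffers, network$buffers)

  structure(list(network = network, config = config,
                 standardize = list(mean = mu, sd = sdv),
                 history = do.call(rbind, hist), best_epoch = best_epoch,
                 n_train = length(tidx), n_val = length(vidx)),
            class = "selfonn_fit")
}

eval_loss_acc <- function(network, x, y, batch_size = 32L, handle = NULL) {
  if (is.null(handle)) handle <- cpp_net_create(unclass(network$arch))
  n <- nrow(x)
  loss <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(t(x[idx, , drop = FALSE]), dim = c(1L, ncol(x), length(idx)))
    lp <- cpp_net_forward_h(handle, network$params, network$buffers, xb, FALSE)
    loss <- loss + softm_mse_loss(lp, y[idx]) * length(idx)
    correct <- correct + sum(max.col(t(lp), ties.method = "first") - 1L == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' @export
print.selfonn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %s (Q = %d): %d epochs, %d train / %d val segments\n",
              if (x$network$arch$attention_enabled) "Self-ResAttentioNet18" else "Self-ResNet18",
              x$network$arch$taylor_order, nrow(h), x$n_train, x$n_val))
  cat(sprintf("  best epoch %d: val loss %.4f, val accuracy %.3f\n",
              x$best_epoch, h$val_loss[x$best_epoch], h$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
predict.selfonn_fit <- function(object, x, type = c("log_prob", "prob", "class"),
                                ...) {
  type <- match.arg(type)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  xs <- (x - object$standardize$mean) / object$standardize$sd
  predict(object$network, xs, type = type, ...)
}

#' Learning curves of a fit
#'
#' Plots train/validation loss and accuracy against epoch.
#'
#' @param x a `selfonn_fit`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.selfonn_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l", lty = 1,
                    xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), col = 1:2, lty = 1)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", main = "Loss", ...)
  graphics::legend("topright", c("train", "validation"), col = 1:2, lty = 1)
  invisible(x)
}

#' Evaluate a trained fold on held-out segments
#'
#' Applies the fit's standardization, predicts every test segment, and
#' assembles the weighted classification report (confusion counts, weighted
#' precision/recall/F1/specificity, overall accuracy, ROC curve and AUC).
#'
#' @param fit a `selfonn_fit` from [train_fold()].
#' @param segments test segments, matrix with one segment per row;
#'   must come from sessions unseen during training (the session-independent
#'   contract) and be non-overlapping.
#' @param labels 0-based integer labels for the test segments.
#' @return A `classification_report`; see [classification_report()].
#' @export
evaluate_fold <- function(fit, segments, labels) {
  stopifnot(inherits(fit, "selfonn_fit"))
  if (!is.matrix(segments) || nrow(segments) == 0L) stop("non-empty test set required")
  probs <- predict(fit, segments, type = "prob")
  preds <- max.col(probs, ties.method = "first") - 1L
  classification_report(as.integer(labels), preds, scores = probs[, 2L])
}
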