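#' Training configuration
#'
#' The training protocol: Adam (learning rate `1e-3`), sparse categorical
#' cross-entropy on integer labels, batch size 16, at most 50 epochs with
#' early stopping on validation loss (patience 10, best weights restored)
#' and learning-rate reduction by a factor of 0.1 after a 3-epoch plateau;
#' 20% of the training data is held out as a validation split.
#'
#' @param learning_rate Initial Adam learning rate (default `1e-3`).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Maximum epochs (default 50).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (default 10).
#' @param lr_reduce_factor Multiplicative LR decay on plateau (default 0.1).
#' @param lr_reduce_patience Plateau length triggering LR decay (default 3).
#' @param validation_fraction Fraction of the training set held out for
#'   validation (default 0.2).
#' @param seed Integer seed for weight init, shuffling and splits.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         max_epochs = 50L, early_stop_patience = 10L,
                         lr_reduce_factor = 0.1, lr_reduce_patience = 3L,
                         validation_fraction = 0.2, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  if (early_stop_patience < 1L || lr_reduce_patience < 1L) {
    stop("patience values must be >= 1")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split a dataset into train and test sets
#'
#' A seeded uniform random split without per-class stratification; the two
#' parts are disjoint and exhaustive and the train part has
#' `floor(train_fraction * n)` items.
#'
#' @param dataset A [labeled_image_set()].
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n <- n_items(dataset)
  if (n == 0L) stop("cannot split an empty dataset")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_train <- floor(train_fraction * n)
  perm <- sample(n)
  list(train = subset_items(dataset, sort(perm[seq_len(n_train)])),
       test = subset_items(dataset, sort(perm[-seq_len(n_train)])))
}

eval_loss_acc <- function(model, x, labels, batch_size = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batch_size - 1L, n)
    p <- model_forward(model, x[, , , idx, drop = FALSE])$out
    loss <- loss + sum(-log(pmax(p[cbind(seq_along(idx), labels[idx])], 1e-12)))
    correct <- correct + sum(max.col(p, ties.method = "first") == labels[idx])
    at <- at + batch_size
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a model
#'
#' Mini-batch Adam training with sparse categorical cross-entropy, a seeded
#' validation holdout, early stopping (restoring the best-validation-loss
#' weights) and reduce-LR-on-plateau.  Pixel inputs are rescaled by 1/255;
#' aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param model A [init_model()] object ending in softmax.
#' @param train_set A pixel-space [labeled_image_set()].
#' @param config A [train_config()].
#' @param verbose Print a line per epoch?
#' @return List with `model` (best weights restored), `history` (data.frame
#'   `epoch`, `train_loss`, `val_loss`, `train_acc`, `val_acc`, `lr`),
#'   `epochs_run`, `stopped_epoch` (epoch of the restored weights).
#' @export
train_model <- function(model, train_set, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- n_items(train_set)
  n_val <- max(1L, floor(config$validation_fraction * n))
  perm <- sample(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  x_tr <- train_set$images[, , , tr_idx, drop = FALSE] / 255
  y_tr <- train_set$labels[tr_idx]
  x_val <- train_set$images[, , , val_idx, drop = FALSE] / 255
  y_val <- train_set$labels[val_idx]

  state <- adam_init(model$weights)
  lr <- config$learning_rate
  best <- list(loss = Inf, weights = model$weights, epoch = 0L)
  wait_stop <- 0L; wait_lr <- 0L
  hist <- data.frame()
  t_step <- 0L
  n_tr <- length(y_tr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n_tr)
    ep_loss <- 0; ep_correct <- 0
    at <- 1L
    while (at <= n_tr) {
      idx <- ord[at:min(at + config$batch_size - 1L, n_tr)]
      xb <- x_tr[, , , idx, drop = FALSE]
      yb <- y_tr[idx]
      fw <- model_forward(model, xb, training = TRUE, keep_all = TRUE)
      bw <- model_backward(model, fw$cache, yb)
      if (!is.finite(bw$loss)) {
        stop(sprintf("training diverged (loss = %s) at epoch %d; reduce the learning rate",
                     bw$loss, epoch))
      }
      t_step <- t_step + 1L
      upd <- adam_step(model, bw$grads, bw$bn_updates, state, lr, t_step)
      model <- upd$model; state <- upd$state
      ep_loss <- ep_loss + bw$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fw$out, ties.method = "first") == yb)
      at <- at + config$batch_size
    }
    val <- eval_loss_acc(model, x_val, y_val)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / n_tr, val_loss = val$loss,
      train_acc = ep_correct / n_tr, val_acc = val$acc, lr = lr))
    if (verbose) {
      message(sprintf("epoch %02d  loss %.4f  val_loss %.4f  val_acc %.3f  lr %.2g",
                      epoch, ep_loss / n_tr, val$loss, val$acc, lr))
    }
    if (val$loss < best$loss - 1e-6) {
      best <- list(loss = val$loss, weights = model$weights, epoch = epoch)
      wait_stop <- 0L; wait_lr <- 0L
    } else {
      wait_stop <- wait_stop + 1L
      wait_lr <- wait_lr + 1L
      if (wait_lr >= config$lr_reduce_patience) {
        lr <- lr * config$lr_reduce_factor
        wait_lr <- 0L
      }
      if (wait_stop >= config$early_stop_patience) break
    }
  }
  model$weights <- best$weights
  list(model = model, history = hist, epochs_run = nrow(hist),
       stopped_epoch = best$epoch)
}

#' Predict class probabilities
#'
#' @param object A trained `cnn_model`.
#' @param images Array `(H, W, C, N)` of raw 0-255 images (rescaled
#'   internally) or a [labeled_image_set()].
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return Matrix `(N, n_classes)` of probabilities.
#' @export
predict.cnn_model <- function(object, images, batch_size = 64L, ...) {
  if (inherits(images, "labeled_image_set")) images <- images$images
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  out <- NULL
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batch_size - 1L, n)
    p <- model_forward(object, images[, , , idx, drop = FALSE] / 255)$out
    if (is.null(out)) out <- matrix(0, n, ncol(p))
    out[idx, ] <- p
    at <- at + batch_size
  }
  out
}

#' Classification metrics report
#'
#' Computes the confusion matrix and support-weighted precision, recall and
#' F1 together with overall accuracy, all as percentages rounded to two
#' decimals.  Weighted recall coincides with accuracy by construction.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors
#'   (1-based class indices).
#' @param n_classes Number of classes.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (percent) and `confusion` (true x
#'   predicted integer matrix).
#' @export
compute_metrics <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  lev <- seq_len(n_classes)
  conf <- table(factor(true_labels, levels = lev),
                factor(predicted_labels, levels = lev))
  conf <- matrix(as.integer(conf), n_classes, n_classes,
                 dimnames = list(true = lev, predicted = lev))
  support <- rowSums(conf)
  tp <- diag(conf)
  prec_c <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / sum(support)
  structure(list(
    accuracy = round(100 * sum(tp) / sum(conf), 2),
    precision = round(100 * sum(w * prec_c), 2),
    recall = round(100 * sum(w * rec_c), 2),
    f1 = round(100 * sum(w * f1_c), 2),
    confusion = conf
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a model on a test set
#'
#' @param model A trained `cnn_model`.
#' @param test_set A pixel-space [labeled_image_set()].
#' @return A [compute_metrics()] report.
#' @export
evaluate_model <- function(model, test_set) {
  probs <- predict(model, test_set)
  pred <- max.col(probs, ties.method = "first")
  compute_metrics(test_set$labels, pred, length(test_set$class_names))
}
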