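#' Classification task specification
#'
#' The five study tasks over the label space of the dose-difference images:
#' * `TF_DETECT` - error-free vs TF error (positive = TF; both signs, all
#'   magnitudes).
#' * `DLG_DETECT` - error-free vs DLG error (positive = DLG).
#' * `TF_VS_DLG` - TF error vs DLG error (positive = TF; error-free images
#'   are excluded).
#' * `TF_SIGN` - positive vs negative TF error (positive class = `+`).
#' * `DLG_SIGN` - positive vs negative DLG error (positive class = `+`).
#'
#' @param task Task name.
#' @return An object of class `task_spec` with `include(manifest)` and
#'   `positive(manifest)` predicate functions.
#' @export
task_spec <- function(task = c("TF_DETECT", "DLG_DETECT", "TF_VS_DLG",
                               "TF_SIGN", "DLG_SIGN")) {
  task <- match.arg(task)
  def <- switch(task,
    TF_DETECT  = list(include = function(m) m$error_type %in% c("error_free", "TF"),
                      positive = function(m) m$error_type == "TF"),
    DLG_DETECT = list(include = function(m) m$error_type %in% c("error_free", "DLG"),
                      positive = function(m) m$error_type == "DLG"),
    TF_VS_DLG  = list(include = function(m) m$error_type %in% c("TF", "DLG"),
                      positive = function(m) m$error_type == "TF"),
    TF_SIGN    = list(include = function(m) m$error_type == "TF",
                      positive = function(m) m$sign == "+"),
    DLG_SIGN   = list(include = function(m) m$error_type == "DLG",
                      positive = function(m) m$sign == "+"))
  structure(list(task = task, include = def$include, positive = def$positive,
                 augment_class = if (grepl("DETECT", task)) "error_free" else NA),
            class = "task_spec")
}

#' Training configuration
#'
#' The optimizer is plain stochastic gradient descent with momentum; the
#' study grid uses batch sizes 8 and 16 and learning rates 0.001 and 0.0001
#' over 50 epochs. The desk-scale backbone is a three-block convolutional
#' network trained from scratch on one-channel images downsampled to
#' `input_size`.
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 8).
#' @param learning_rate SGD learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param lr_schedule `"cosine"` (half-cosine decay of the learning rate to
#'   zero over the epochs; stabilizes the final model) or `"constant"`.
#' @param backbone `"small_cnn"` or `"small_cnn_wide"`.
#' @param input_size Image size after mean-pooling the 256 x 256 inputs
#'   (must divide 256; default 64).
#' @param augment_factor Expansion factor for the error-free training class
#'   in detection tasks (default 6, which balances 1 error-free variant
#'   against 2 signs x 3 magnitudes).
#' @param seed Global seed controlling weight init, shuffling and
#'   augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 8, learning_rate = 0.001,
                         momentum = 0.9, lr_schedule = c("cosine", "constant"),
                         backbone = "small_cnn", input_size = 64,
                         augment_factor = 6, seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop_named("vmatqa_invalid_config",
               "epochs >= 1, batch_size >= 1 and learning_rate > 0 required")
  if (!backbone %in% names(cnn_backbones()))
    stop_named("vmatqa_invalid_config",
               sprintf("unknown backbone '%s'", backbone))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lr_schedule = lr_schedule,
                 backbone = backbone, input_size = as.integer(input_size),
                 augment_factor = as.integer(augment_factor),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @keywords internal
#' @noRd
load_pixels <- function(paths) lapply(paths, read_png_image)

# pixels (0..255) -> pooled [-1, 1] stack (H, W, N)
#' @keywords internal
#' @noRd
pixels_to_stack <- function(pixel_list, input_size) {
  n <- length(pixel_list)
  stopifnot(n > 0)
  f <- nrow(pixel_list[[1]]) / input_size
  stopifnot(f == round(f))
  x <- array(0, c(input_size, input_size, n))
  for (k in seq_len(n))
    x[, , k] <- pool_mean((pixel_list[[k]] - 128) / 128, f)
  x
}

#' @keywords internal
#' @noRd
load_task_data <- function(task, manifest, config, augment = FALSE) {
  keep <- task$include(manifest)
  m <- manifest[keep, , drop = FALSE]
  if (!nrow(m))
    stop_named("vmatqa_empty_dataset", "no images match the task definition")
  y <- as.integer(task$positive(m))
  px <- load_pixels(m$path)
  if (augment && !is.na(task$augment_class) && config$augment_factor > 1) {
    aug_sel <- which(m$error_type == "error_free")
    if (length(aug_sel)) {
      aug <- augment_error_free(px[aug_sel], config$augment_factor,
                                seed = config$seed, split = m$split[aug_sel])
      px <- c(px[-aug_sel], aug)
      y <- c(y[-aug_sel], rep(0L, length(aug)))
      m <- rbind(m[-aug_sel, , drop = FALSE],
                 m[rep(aug_sel, each = config$augment_factor), , drop = FALSE])
    }
  }
  list(x = pixels_to_stack(px, config$input_size), y = y, manifest = m)
}

#' Train a CNN classifier for one task
#'
#' Trains the configured backbone from scratch with SGD + momentum and
#' two-class cross-entropy. For detection tasks the error-free training
#' class is augmented by `config$augment_factor` to balance the classes.
#' Training is deterministic under a fixed seed, data and backbone. When a
#' test manifest is supplied, test loss/accuracy are tracked per epoch
#' (learning curves).
#'
#' @param task A [task_spec()] or task name.
#' @param train_manifest Manifest data frame of the training split.
#' @param config A [train_config()].
#' @param test_manifest Optional manifest of the test split for learning
#'   curves.
#' @return An object of class `vmat_classifier`: network weights, config,
#'   task, and a `curves` data frame with one row per epoch.
#' @export
train_classifier <- function(task, train_manifest, config = train_config(),
                             test_manifest = NULL) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"), inherits(config, "train_config"))
  data <- load_task_data(task, train_manifest, config, augment = TRUE)
  if (length(unique(data$y)) < 2)
    stop_named("vmatqa_single_class",
               "training set contains a single class")
  test <- if (!is.null(test_manifest))
    load_task_data(task, test_manifest, config, augment = FALSE)

  set.seed(config$seed)
  net <- cnn_init(config$input_size, cnn_backbones()[[config$backbone]])
  vel <- cnn_zero_velocity(net)
  n <- length(data$y)
  curves <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       train_accuracy = NA_real_, test_loss = NA_real_,
                       test_accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    lr <- if (identical(config$lr_schedule, "constant")) config$learning_rate
          else config$learning_rate * 0.5 *
            (1 + cos(pi * (ep - 1) / config$epochs))
    ord <- sample.int(n)
    loss_sum <- 0; correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- data$x[, , idx, drop = FALSE]
      dim(xb) <- c(dim(xb)[1], dim(xb)[2], length(idx), 1L)
      yb <- data$y[idx]
      fwd <- cnn_forward(net, xb, train = TRUE)
      p <- pmax(fwd$probs[cbind(seq_along(idx), yb + 1L)], 1e-12)
      loss_sum <- loss_sum - sum(log(p))
      correct <- correct + sum((fwd$probs[, 2] > 0.5) == (yb == 1))
      onehot <- matrix(0, length(idx), 2)
      onehot[cbind(seq_along(idx), yb + 1L)] <- 1
      grads <- cnn_backward(net, fwd, onehot)
      upd <- cnn_sgd_step(net, grads, vel, lr, config$momentum)
      net <- upd$net; vel <- upd$vel
    }
    curves$train_loss[ep] <- loss_sum / n
    curves$train_accuracy[ep] <- 100 * correct / n
    if (!is.null(test_manifest)) {
      sc <- cnn_scores(net, test$x)
      pt <- pmax(ifelse(test$y == 1, sc, 1 - sc), 1e-12)
      curves$test_loss[ep] <- -mean(log(pt))
      curves$test_accuracy[ep] <- 100 * mean((sc > 0.5) == (test$y == 1))
    }
  }
  structure(list(net = net, config = config, task = task, curves = curves),
            class = "vmat_classifier")
}

#' @export
print.vmat_classifier <- function(x, ...) {
  cat(sprintf("<vmat_classifier> task %s, backbone %s, %d epochs (final train acc %.1f%%)\n",
              x$task$task, x$config$backbone, x$config$epochs,
              utils::tail(x$curves$train_accuracy, 1)))
  invisible(x)
}

#' Positive-class scores of a trained classifier
#'
#' @param object A `vmat_classifier`.
#' @param manifest Manifest data frame of images to score.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities for the included
#'   rows, with the filtered manifest as attribute `manifest`.
#' @export
predict.vmat_classifier <- function(object, manifest, ...) {
  data <- load_task_data(object$task, manifest, object$config,
                         augment = FALSE)
  out <- cnn_scores(object$net, data$x)
  attr(out, "manifest") <- data$manifest
  attr(out, "y") <- data$y
  out
}

#' Save / load a trained classifier
#'
#' Serialization round-trips exactly: the reloaded model produces identical
#' predictions.
#'
#' @param model A `vmat_classifier`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "vmat_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)

#' @keywords internal
#' @noRd
metrics_from_scores <- function(scores, y, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  auc <- if (length(unique(y)) == 2) {
    r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  } else NA_real_
  list(accuracy = 100 * (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       auc = auc,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(truth = c("neg", "pos"),
                                          predicted = c("neg", "pos"))))
}

#' Evaluate a trained classifier on a test manifest
#'
#' Metrics are computed from the confusion matrix at score threshold 0.5
#' (accuracy, sensitivity, specificity, in percent) plus the threshold-free
#' AUC from the score ranking.
#'
#' @param model A `vmat_classifier`.
#' @param test_manifest Manifest data frame of the test split.
#' @return An object of class `eval_report`.
#' @export
evaluate_classifier <- function(model, test_manifest) {
  if (is.null(test_manifest) || !nrow(test_manifest))
    stop_named("vmatqa_empty_dataset", "test set is empty")
  scores <- predict(model, test_manifest)
  y <- attr(scores, "y")
  m <- metrics_from_scores(as.numeric(scores), y)
  structure(c(m, list(n = length(y), task = model$task$task,
                      curves = model$curves)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: acc %.1f%%, sens %.1f%%, spec %.1f%%, AUC %.3f (n=%d)\n",
              x$task, x$accuracy, x$sensitivity, x$specificity, x$auc, x$n))
  invisible(x)
}

#' Per-magnitude or per-site metric breakdown
#'
#' Restricts the positive class of a detection task to one magnitude (the
#' error-free negatives are kept in full) or restricts both classes to one
#' site, and recomputes the metric set per subset from the same trained
#' model.
#'
#' @param model A `vmat_classifier`.
#' @param test_manifest Manifest data frame of the test split.
#' @param by `"magnitude"` or `"site"`.
#' @return Data frame of metrics per subset level.
#' @export
evaluate_breakdown <- function(model, test_manifest, by = c("magnitude", "site")) {
  by <- match.arg(by)
  scores <- predict(model, test_manifest)
  y <- attr(scores, "y")
  m <- attr(scores, "manifest")
  s <- as.numeric(scores)
  levels <- if (by == "magnitude") {
    sort(unique(m$magnitude_pct[m$magnitude_pct > 0]))
  } else sort(unique(m$site))
  rows <- lapply(levels, function(lv) {
    sel <- if (by == "magnitude") m$magnitude_pct %in% c(0, lv) else m$site == lv
    met <- metrics_from_scores(s[sel], y[sel])
    data.frame(level = as.character(lv), n = sum(sel),
               accuracy = met$accuracy, sensitivity = met$sensitivity,
               specificity = met$specificity, auc = met$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$by <- by
  out
}

#' Hyperparameter / task grid evaluation
#'
#' Trains and evaluates one model per combination of task, sigma setting,
#' batch size, learning rate and backbone, reproducing the study's results
#' table shape (train and test accuracy, sensitivity, specificity, AUC).
#'
#' @param splits Named list: one entry per sigma (name = sigma value), each
#'   a list with `train` and `test` manifests (e.g. from [split_by_plan()]
#'   applied per sigma subset).
#' @param tasks Character vector of task names.
#' @param batch_sizes,learning_rates,backbones Grid axes.
#' @param epochs,input_size,augment_factor,seed Passed to [train_config()].
#' @return Data frame with one row per grid point.
#' @export
grid_evaluate <- function(splits, tasks = c("TF_DETECT", "DLG_DETECT"),
                          batch_sizes = c(8, 16),
                          learning_rates = c(0.001, 0.0001),
                          backbones = "small_cnn", epochs = 50,
                          input_size = 64, augment_factor = 6, seed = 1) {
  rows <- list()
  for (task in tasks) for (sg in names(splits))
    for (bs in batch_sizes) for (lr in learning_rates)
      for (bb in backbones) {
        cfg <- train_config(epochs = epochs, batch_size = bs,
                            learning_rate = lr, backbone = bb,
                            input_size = input_size,
                            augment_factor = augment_factor, seed = seed)
        model <- train_classifier(task, splits[[sg]]$train, cfg)
        rep_te <- evaluate_classifier(model, splits[[sg]]$test)
        rep_tr <- evaluate_classifier(model, splits[[sg]]$train)
        rows[[length(rows) + 1]] <- data.frame(
          task = task, sigma = as.numeric(sg), batch_size = bs,
          learning_rate = lr, backbone = bb,
          train_accuracy = rep_tr$accuracy, test_accuracy = rep_te$accuracy,
          test_sensitivity = rep_te$sensitivity,
          test_specificity = rep_te$specificity, test_auc = rep_te$auc,
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}
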