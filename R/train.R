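# Training: SGD with momentum and weight decay, per-epoch validation,
# checkpoint-best early stopping; evaluation through the confusion-matrix
# metric suite.

#' Training protocol configuration
#'
#' Defaults follow the stochastic-gradient-descent protocol used for the
#' full-scale experiments: momentum 0.9, weight decay 0.001, initial
#' learning rate 0.01, 300 epochs, batch size 2, early stopping on
#' validation overall accuracy with patience 30.
#'
#' @param epochs Maximum number of epochs.
#' @param batch_size Patches per gradient step (partial trailing batches are
#'   dropped during training).
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient applied to convolution/dense
#'   weight matrices (not to biases or batch-norm parameters).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping; the best-validation parameters are retained.
#' @param lr_schedule `"constant"` or `"step"` decay.
#' @param lr_step,lr_gamma Step size (epochs) and decay factor of the step
#'   schedule.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param verbose Print one line per epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 2L, lr = 0.01,
                         momentum = 0.9, weight_decay = 0.001,
                         early_stopping_patience = 30L,
                         lr_schedule = c("constant", "step"),
                         lr_step = 100L, lr_gamma = 0.1,
                         seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, momentum >= 0,
            momentum < 1, weight_decay >= 0, early_stopping_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 lr_schedule = lr_schedule, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "train_config")
}

# stack a list of patches into model tensors; the NDVI regression target is
# only assembled when training needs it
patches_to_tensors <- function(patches, config, need_ndvi = TRUE) {
  n <- length(patches)
  H <- config$patch_size; T <- config$n_dates; B <- config$n_bands
  HW <- H * H
  x <- array(0, c(B, HW * T, n))
  labs <- matrix(0L, HW, n)
  nd <- matrix(0, HW * T, n)
  for (i in seq_len(n)) {
    p <- patches[[i]]
    d <- dim(p$reflectance)
    if (d[1] != T || d[2] != B || d[3] != H || d[4] != H) {
      stop(sprintf("patch %s has shape (T=%d,B=%d,%dx%d); model expects (T=%d,B=%d,%dx%d)",
                   p$patch_id, d[1], d[2], d[3], d[4], T, B, H, H))
    }
    x[, , i] <- vol_from_reflectance(p$reflectance)[, , 1]
    labs[, i] <- as.integer(p$labels)
    if (need_ndvi) {
      nv <- if (!is.null(p$ndvi)) p$ndvi else ndvi_series(p)$values
      nd[, i] <- as.vector(aperm(nv, c(2, 3, 1)))
    }
  }
  list(x = x, labs = labs, ndvi = nd, n = n)
}

argmax_cols <- function(mat) {
  max.col(t(mat), ties.method = "first") - 1L
}

# batched label prediction; returns (HW, n) integer matrix of 0-based labels
predict_labels_internal <- function(model, tensors, batch = 16L) {
  n <- tensors$n
  HW <- model$config$patch_size^2
  out <- matrix(0L, HW, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    fw <- model_forward(model, tensors$x[, , i:j, drop = FALSE],
                        N = j - i + 1L, train = FALSE, keep_cache = FALSE)
    K <- model$config$n_classes
    out[, i:j] <- matrix(argmax_cols(matrix(fw$logits, K,
                                            HW * (j - i + 1L))), HW)
    i <- j + 1L
  }
  out
}

sgd_update <- function(model, state, lr, momentum, wd) {
  layers <- model_layers(model)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (pn in names(l$par)) {
      key <- paste(nm, pn, sep = "|")
      g <- l$grad[[pn]]
      if (wd > 0 && pn == "W") g <- g + wd * l$par[[pn]]
      v <- state[[key]]
      v <- if (is.null(v)) -lr * g else momentum * v - lr * g
      state[[key]] <- v
      l$par[[pn]] <- l$par[[pn]] + v
    }
  }
  invisible(NULL)
}

#' Train a (3+2)D SAFPN model
#'
#' Fits the network with seeded stochastic gradient descent on the combined
#' focal + NDVI objective, evaluating overall accuracy on the validation
#' patches after every epoch, and returns the parameters of the best
#' validation epoch.
#'
#' @param train,val Lists of [ts_patch()] objects (non-empty).
#' @param config A [safpn_config()] matching the patches' shape.
#' @param loss A [loss_config()].
#' @param control A [train_config()].
#' @param model Optional pre-built [safpn_model()] to continue training.
#' @return Object of class `safpn_fit` with elements `model`, `history`
#'   (per-epoch data frame: epoch, loss, focal, mse, val_oa, lr),
#'   `best_epoch`, `best_val_oa`, and the three configuration objects.
#' @export
safpn_train <- function(train, val, config = safpn_config(),
                        loss = loss_config(), control = train_config(),
                        model = NULL, .tensors = NULL) {
  if (length(train) == 0 && is.null(.tensors)) stop("empty training subset")
  if (length(val) == 0 && is.null(.tensors)) stop("empty validation subset")
  if (length(loss$alpha) < config$n_classes) {
    stop("loss alpha vector shorter than n_classes")
  }
  if (is.null(model)) model <- safpn_model(config, seed = control$seed)
  # .tensors: pre-stacked tensors (list with train/val) so repeated runs on
  # one dataset skip the conversion
  tr <- if (!is.null(.tensors)) .tensors$train else
    patches_to_tensors(train, config)
  va <- if (!is.null(.tensors)) .tensors$val else
    patches_to_tensors(val, config)
  set.seed(control$seed + 1L)
  state <- new.env(parent = emptyenv())
  bs <- control$batch_size
  nb <- tr$n %/% bs
  if (nb == 0) stop(sprintf("batch_size %d exceeds the %d training patches",
                            bs, tr$n))
  hist <- data.frame(epoch = integer(), loss = numeric(), focal = numeric(),
                     mse = numeric(), val_oa = numeric(), lr = numeric())
  best_oa <- -Inf; best_snap <- NULL; best_epoch <- 0L; stall <- 0L
  for (ep in seq_len(control$epochs)) {
    lr <- if (control$lr_schedule == "step") {
      control$lr * control$lr_gamma^((ep - 1L) %/% control$lr_step)
    } else control$lr
    ord <- sample(tr$n)
    tot <- foc <- msev <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(b - 1L) * bs + seq_len(bs)]
      zero_grads(model)
      fw <- model_forward(model, tr$x[, , idx, drop = FALSE], N = bs,
                          train = TRUE)
      bl <- batch_loss_grad(fw$logits, fw$ndvi, tr$labs[, idx],
                            tr$ndvi[, idx, drop = FALSE], loss)
      if (!is.finite(bl$total)) {
        stop(sprintf("non-finite loss at epoch %d batch %d (focal %.4g, mse %.4g)",
                     ep, b, bl$focal, bl$mse))
      }
      model_backward(model, fw$cache, bl$dlogits, bl$dndvi, bs)
      sgd_update(model, state, lr, control$momentum, control$weight_decay)
      tot <- tot + bl$total; foc <- foc + bl$focal; msev <- msev + bl$mse
    }
    pl <- predict_labels_internal(model, va)
    val_oa <- mean(pl == va$labs)
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / nb,
                                   focal = foc / nb, mse = msev / nb,
                                   val_oa = val_oa, lr = lr))
    if (control$verbose) {
      message(sprintf("epoch %3d | loss %.4f (focal %.4f, mse %.4f) | val OA %.4f | lr %g",
                      ep, tot / nb, foc / nb, msev / nb, val_oa, lr))
    }
    if (val_oa > best_oa) {
      best_oa <- val_oa
      best_snap <- params_get(model)
      best_epoch <- ep
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$early_stopping_patience) break
    }
  }
  if (!is.null(best_snap)) params_set(model, best_snap)
  structure(list(model = model, history = hist, best_epoch = best_epoch,
                 best_val_oa = best_oa, config = config, loss = loss,
                 control = control, n_train = tr$n, n_val = va$n),
            class = "safpn_fit")
}

#' @export
print.safpn_fit <- function(x, ...) {
  cat(sprintf("(3+2)D %s: %s stages %s, pyramid %d, %d classes, T=%d, %d params\n",
              if (x$config$use_sa) "SAFPN" else "FPN (no split-attention)",
              x$config$stage_depth_preset,
              paste(x$config$stage_channels, collapse = "-"),
              x$config$pyramid_channels, x$config$n_classes,
              x$config$n_dates, safpn_num_params(x$model)))
  cat(sprintf("trained %d epoch(s) on %d patches; best val OA %.4f at epoch %d\n",
              nrow(x$history), x$n_train, x$best_val_oa, x$best_epoch))
  invisible(x)
}

#' @export
summary.safpn_fit <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("final training loss %.4f (focal %.4f, mse %.4f)\n",
              h$loss[nrow(h)], h$focal[nrow(h)], h$mse[nrow(h)]))
  invisible(object)
}

#' Predict from a fitted model
#'
#' @param object A [safpn_train()] fit.
#' @param newdata A [ts_patch()], a list of them, or a `(T, B, H, W)` array.
#' @param type `"class"` (integer H x W label map, 0-based), `"prob"`
#'   (`n_classes x H x W` softmax probabilities), or `"ndvi"`
#'   (`T x H x W` regression-head output).
#' @param ... Unused.
#' @return A single map (or a list of maps when `newdata` is a list).
#' @export
predict.safpn_fit <- function(object, newdata, type = c("class", "prob", "ndvi"),
                              ...) {
  type <- match.arg(type)
  one <- function(p) {
    fw <- safpn_forward(object$model, p)
    H <- object$config$patch_size
    switch(type,
           class = matrix(argmax_cols(matrix(fw$logits,
                                             object$config$n_classes, H * H)),
                          H, H),
           prob = {
             pr <- softmax_cols(matrix(fw$logits, object$config$n_classes,
                                       H * H))
             array(pr, c(object$config$n_classes, H, H))
           },
           ndvi = fw$ndvi)
  }
  if (is.list(newdata) && !inherits(newdata, "ts_patch")) {
    lapply(newdata, one)
  } else one(newdata)
}

#' @export
plot.safpn_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "objective", ...)
  graphics::lines(h$epoch, h$focal, lty = 2)
  graphics::lines(h$epoch, h$mse, lty = 3)
  graphics::legend("topright", c("total", "focal", "mse"), lty = 1:3,
                   bty = "n", cex = 0.8)
  graphics::plot(h$epoch, h$val_oa, type = "l", xlab = "epoch",
                 ylab = "validation OA", ylim = c(0, 1), main = "validation")
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}

#' Evaluate a model on a set of patches
#'
#' Runs deterministic inference (argmax over the class logits), accumulates
#' the confusion matrix over all pixels, and derives the metric suite.
#'
#' @param fit A `safpn_fit` (or a bare [safpn_model()]).
#' @param patches List of [ts_patch()] with labels.
#' @param ignore Optional class ids excluded from the confusion matrix.
#' @param batch Inference batch size.
#' @return List with `confusion` ([confusion_counts()] matrix), `metrics`
#'   ([classification_metrics()] report), and `predicted` (list of label
#'   maps).
#' @export
evaluate_model <- function(fit, patches, ignore = NULL, batch = 16L) {
  model <- if (inherits(fit, "safpn_fit")) fit$model else fit
  te <- patches_to_tensors(patches, model$config, need_ndvi = FALSE)
  pl <- predict_labels_internal(model, te, batch)
  cm <- confusion_counts(as.integer(pl), as.integer(te$labs),
                         model$config$n_classes, ignore = ignore)
  H <- model$config$patch_size
  list(confusion = cm, metrics = classification_metrics(cm),
       predicted = lapply(seq_len(te$n), function(i) matrix(pl[, i], H, H)))
}
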