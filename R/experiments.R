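# Desk-scale benchmark experiments: a reduced-width network trained on the
# default synthetic eight-class phenology dataset, plus the four-way
# ablation (with/without split-attention, focal vs plain cross-entropy).
# Problem sizes and budgets are fixed here (largest runs that keep the whole
# suite inside a single-CPU session); the methods vignette discusses the
# choices.

#' Default synthetic benchmark dataset
#'
#' 200 training, 60 validation and 60 test patches of 24 px drawn from the
#' default eight-class recipe ([talhu_recipe()], NDVI noise 0.05), rendered
#' in memory.
#'
#' @param seed Integer seed.
#' @param n_train,n_val,n_test Patch counts per subset.
#' @return List with elements `train`, `val`, `test` (lists of
#'   [ts_patch()]) and `recipe`.
#' @export
desk_benchmark_data <- function(seed = 1L, n_train = 200L, n_val = 60L,
                                n_test = 60L) {
  seed <- as.integer(seed)
  recipe <- talhu_recipe(noise_sd = 0.05, seed = seed)
  list(train = render_patch_set(recipe, n_train, 24L, seed = seed),
       val = render_patch_set(recipe, n_val, 24L, seed = seed + 20011L),
       test = render_patch_set(recipe, n_test, 24L, seed = seed + 40009L),
       recipe = recipe)
}

#' Reduced-width network configurations for desk-scale runs
#'
#' `desk_safpn_config()` uses stage widths 32-64-128-256 with a 32-channel
#' pyramid and a 16-channel stem; `desk_ablation_config()` halves the widths
#' again (8-16-32-32, pyramid 16, stem 6) so the four-way ablation stays
#' affordable on one CPU.
#'
#' @param use_sa Include the split-attention modules (`FALSE` gives the
#'   plain-FPN baseline).
#' @return A [safpn_config()].
#' @export
desk_safpn_config <- function(use_sa = TRUE) {
  safpn_config(stage_channels = c(32L, 64L, 128L, 256L),
               pyramid_channels = 32L, n_classes = 8L, n_dates = 20L,
               n_bands = 4L, patch_size = 24L, stem_channels = 16L,
               use_sa = use_sa, sa = sa_config(radix = 4L),
               stage_depth_preset = "plain")
}

#' @rdname desk_safpn_config
#' @export
desk_ablation_config <- function(use_sa = TRUE) {
  safpn_config(stage_channels = c(8L, 16L, 32L, 32L),
               pyramid_channels = 16L, n_classes = 8L, n_dates = 20L,
               n_bands = 4L, patch_size = 24L, stem_channels = 6L,
               use_sa = use_sa, sa = sa_config(radix = 4L),
               stage_depth_preset = "plain")
}

# desk training protocol: batch 8, lr 0.05 with a x0.2 step near the end of
# the budget, best-validation checkpointing
desk_train_control <- function(seed, epochs, lr_step) {
  train_config(epochs = epochs, batch_size = 8L, lr = 0.05,
               lr_schedule = "step", lr_step = lr_step, lr_gamma = 0.2,
               early_stopping_patience = epochs, seed = as.integer(seed))
}

# the focal objective at matched gradient scale: alpha fixes relative class
# weights, focal_weight = 1/mean(alpha) equalizes the step size with the
# unweighted cross-entropy baseline
desk_focal_loss <- function() {
  al <- c(0.05, 0.1, 0.3, 0.3, 0.3, 0.1, 0.1, 0.1)
  loss_config(gamma = 2, alpha = al, ndvi_weight = 1,
              focal_weight = 1 / mean(al))
}

ce_loss_config <- function(n_classes = 8L) {
  loss_config(gamma = 0, alpha = rep(1, n_classes), ndvi_weight = 1)
}

#' Scaled-down learning experiment
#'
#' Trains the reduced-width (3+2)D SAFPN on the default synthetic dataset
#' (200/60/60 patches, T = 20, 24 px) for up to `epochs` epochs (batch 8,
#' SGD momentum 0.9, lr 0.05 with a x0.2 step at epoch 8, focal loss at
#' matched gradient scale) and evaluates the best-validation checkpoint on
#' the held-out test patches.
#'
#' @param seed Integer seed for data generation, initialization and
#'   shuffling.
#' @param epochs Epoch budget.
#' @param data Optional pre-generated [desk_benchmark_data()] result.
#' @param verbose Print per-epoch progress.
#' @return List with `fit`, `val_oa`, `test_oa`, `test_kappa`, `metrics`.
#' @export
run_learning_experiment <- function(seed = 1L, epochs = 12L, data = NULL,
                                    verbose = FALSE) {
  if (is.null(data)) data <- desk_benchmark_data(seed)
  ctrl <- desk_train_control(seed, epochs, lr_step = max(2L, epochs - 4L))
  ctrl$verbose <- isTRUE(verbose)
  fit <- safpn_train(data$train, data$val, desk_safpn_config(TRUE),
                     desk_focal_loss(), ctrl)
  ev <- suppressWarnings(evaluate_model(fit, data$test))
  list(fit = fit, val_oa = fit$best_val_oa, test_oa = ev$metrics$oa,
       test_kappa = ev$metrics$kappa, metrics = ev$metrics)
}

#' Four-way ablation: split-attention and focal loss
#'
#' Trains the four model/loss combinations of the ablation design --
#' plain FPN + cross-entropy, FPN+SA + cross-entropy, FPN + focal,
#' and the full SAFPN (SA + focal) -- on the default synthetic dataset at
#' the reduced ablation widths, each for `epochs` epochs under the shared
#' desk protocol. The full model is repeated over `n_seeds` seeds and
#' summarized by its median test OA; the other variants run once on the
#' base seed.
#'
#' @param seed Base seed.
#' @param n_seeds Number of seeds for the full model.
#' @param epochs Epoch budget per run.
#' @param data Optional pre-generated [desk_benchmark_data()] result.
#' @param verbose Print progress.
#' @return Data frame with columns `variant`, `use_sa`, `loss`, `seed`,
#'   `val_oa`, `test_oa`.
#' @export
run_ablation <- function(seed = 1L, n_seeds = 5L, epochs = 6L, data = NULL,
                         verbose = FALSE) {
  if (is.null(data)) data <- desk_benchmark_data(seed)
  variants <- list(
    fpn_ce = list(use_sa = FALSE, loss = "ce"),
    fpn_sa_ce = list(use_sa = TRUE, loss = "ce"),
    fpn_focal = list(use_sa = FALSE, loss = "focal"),
    safpn = list(use_sa = TRUE, loss = "focal"))
  cfg_cache <- list(
    "TRUE" = desk_ablation_config(TRUE),
    "FALSE" = desk_ablation_config(FALSE))
  tr_tensors <- patches_to_tensors(data$train, cfg_cache[["TRUE"]])
  va_tensors <- patches_to_tensors(data$val, cfg_cache[["TRUE"]])
  te_tensors <- patches_to_tensors(data$test, cfg_cache[["TRUE"]],
                                   need_ndvi = FALSE)
  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    seeds <- if (vn == "safpn") seq.int(seed, length.out = n_seeds) else seed
    for (sd in seeds) {
      ctrl <- desk_train_control(sd, epochs, lr_step = max(2L, epochs - 2L))
      lcfg <- if (v$loss == "ce") ce_loss_config() else desk_focal_loss()
      fit <- safpn_train(data$train, data$val,
                         cfg_cache[[as.character(v$use_sa)]], lcfg, ctrl,
                         .tensors = list(train = tr_tensors,
                                         val = va_tensors))
      pl <- predict_labels_internal(fit$model, te_tensors)
      cm <- confusion_counts(as.integer(pl), as.integer(te_tensors$labs), 8L)
      oa <- suppressWarnings(classification_metrics(cm))$oa
      if (isTRUE(verbose)) {
        message(sprintf("%s seed %d: val OA %.4f, test OA %.4f", vn, sd,
                        fit$best_val_oa, oa))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, use_sa = v$use_sa, loss = v$loss, seed = sd,
        val_oa = fit$best_val_oa, test_oa = oa,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
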