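# Training objective: focal loss on the per-pixel class probabilities plus
# mean squared error on the NDVI regression head.

#' Loss configuration
#'
#' @param gamma Focusing parameter of the focal loss; 0 recovers
#'   alpha-weighted cross-entropy.
#' @param alpha Per-class balancing weights, indexed by class id 0..n-1.
#'   The default is the eight-class vector used for the Talhu-style regime
#'   (low weight on the dominant "others"/maize/sunflower classes, high
#'   weight on the rare crops).
#' @param ndvi_weight Multiplier lambda on the NDVI mean-squared-error term.
#' @param focal_weight Multiplier on the focal term in the combined
#'   objective. The alpha vector fixes the *relative* class weights but also
#'   scales the whole classification gradient; setting
#'   `focal_weight = 1/mean(alpha)` trains the focal objective at the same
#'   effective step size as unweighted cross-entropy, which keeps loss
#'   ablations comparable under a shared learning rate.
#' @param mask_class Optional integer vector of class ids excluded from the
#'   focal term (e.g. `0` to drop the background class from the objective).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(gamma = 2,
                        alpha = c(0.05, 0.1, 0.3, 0.3, 0.3, 0.1, 0.1, 0.1),
                        ndvi_weight = 1,
                        focal_weight = 1,
                        mask_class = NULL) {
  stopifnot(gamma >= 0, all(alpha > 0), all(alpha <= 1), ndvi_weight >= 0,
            focal_weight > 0)
  structure(list(gamma = gamma, alpha = alpha, ndvi_weight = ndvi_weight,
                 focal_weight = focal_weight, mask_class = mask_class),
            class = "loss_config")
}

#' Mean squared error on NDVI predictions
#'
#' Mean over all pixels (and dates) of the squared difference between the
#' predicted and observed NDVI.
#'
#' @param pred,target Numeric arrays of identical shape (typically
#'   `T x H x W`).
#' @return Scalar loss.
#' @export
mse_ndvi <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stop("pred and target must have identical shape")
  }
  if (!all(is.finite(pred)) || !all(is.finite(target))) {
    stop("non-finite values in NDVI loss inputs")
  }
  mean((pred - target)^2)
}

# internal: focal loss and gradient from probabilities
# p: K x m matrix of per-pixel class probabilities, lab: length-m integer 0-based
focal_core <- function(p, lab, cfg, clamp = 1e-8) {
  K <- nrow(p); m <- ncol(p)
  keep <- rep(TRUE, m)
  if (!is.null(cfg$mask_class)) keep <- !(lab %in% cfg$mask_class)
  n_eff <- sum(keep)
  if (n_eff == 0L) return(list(loss = 0, g = numeric(m), pt = numeric(m)))
  pt <- pmax(p[cbind(lab + 1L, seq_len(m))], clamp)
  w <- cfg$alpha[lab + 1L]
  per <- -w * (1 - pt)^cfg$gamma * log(pt)
  per[!keep] <- 0
  loss <- sum(per) / n_eff
  term1 <- if (cfg$gamma > 0) cfg$gamma * (1 - pt)^(cfg$gamma - 1) * log(pt) else 0
  g <- w * (term1 - (1 - pt)^cfg$gamma / pt) / n_eff
  g[!keep] <- 0
  list(loss = loss, g = g, pt = pt)
}

#' Focal loss over a per-pixel probability map
#'
#' `-alpha_t (1 - p_t)^gamma log(p_t)` averaged over pixels, where `p_t` is
#' the probability the model assigns to the true class and `alpha_t` its
#' class balancing weight. `p_t` is clamped below at 1e-8.
#'
#' @param probs Array `(n_classes, H, W)`; each pixel's class vector must sum
#'   to 1 (within 1e-5).
#' @param labels Integer matrix `H x W` with values in `0..n_classes-1`.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, labels, config = loss_config()) {
  d <- dim(probs)
  if (length(d) != 3) stop("probs must be an (n_classes, H, W) array")
  K <- d[1]
  if (!identical(as.integer(d[2:3]), as.integer(dim(labels)))) {
    stop("labels shape must match the spatial shape of probs")
  }
  if (length(config$alpha) < K) stop("alpha vector shorter than n_classes")
  pm <- matrix(probs, K, d[2] * d[3])
  cs <- colSums(pm)
  if (any(abs(cs - 1) > 1e-5)) {
    stop("probs are not a valid per-pixel distribution (columns must sum to 1)")
  }
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) {
    stop(sprintf("labels must lie in [0, %d)", K))
  }
  focal_core(pm, lab, config)$loss
}

#' Combined focal + NDVI objective
#'
#' Applies a per-pixel softmax to the class logits, evaluates the focal term
#' against the labels, adds `ndvi_weight` times the NDVI mean squared error,
#' and returns the total with its per-term breakdown.
#'
#' @param logits Array `(n_classes, H, W)` of unnormalized class scores.
#' @param ndvi_pred,ndvi_true Arrays `(T, H, W)`.
#' @param labels Integer matrix `H x W`, values in `0..n_classes-1`.
#' @param config A [loss_config()].
#' @return List with `total`, `focal`, `mse`.
#' @export
combined_loss <- function(logits, ndvi_pred, ndvi_true, labels,
                          config = loss_config()) {
  d <- dim(logits)
  if (length(d) != 3) stop("logits must be an (n_classes, H, W) array")
  K <- d[1]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) stop(sprintf("labels must lie in [0, %d)", K))
  p <- softmax_cols(matrix(logits, K, d[2] * d[3]))
  fw <- config$focal_weight %||% 1
  focal <- focal_core(p, lab, config)$loss
  mse <- mse_ndvi(ndvi_pred, ndvi_true)
  list(total = fw * focal + config$ndvi_weight * mse, focal = focal,
       mse = mse)
}

# internal: loss + gradients for a training batch
# logits (K, HW, N), ndvi (HWT, N), labs (HW x N integer), ndvi_true (HWT, N)
#
# log(p_t) is evaluated through log-softmax, which is finite for finite
# logits, so the focal term needs no probability clamp here and its
# gradient is exact everywhere (including confidently-wrong pixels, where
# a clamped formulation would flatten the loss and kill the gradient).
batch_loss_grad <- function(logits, ndvi, labs, ndvi_true, cfg) {
  K <- dim(logits)[1]
  m <- length(labs)
  lab <- as.integer(labs)
  zm <- matrix(logits, K, m)
  mx <- zm[1, ]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, zm[k, ])
  e <- exp(zm - rep(mx, each = K))
  s <- colSums(e)
  p <- e * rep(1 / s, each = K)
  logp_t <- zm[cbind(lab + 1L, seq_len(m))] - mx - log(s)
  pt <- exp(logp_t)
  keep <- rep(TRUE, m)
  if (!is.null(cfg$mask_class)) keep <- !(lab %in% cfg$mask_class)
  n_eff <- sum(keep)
  w <- cfg$alpha[lab + 1L]
  per <- -w * (1 - pt)^cfg$gamma * logp_t
  per[!keep] <- 0
  focal <- if (n_eff > 0) sum(per) / n_eff else 0
  term1 <- if (cfg$gamma > 0) {
    ifelse(pt >= 1, 0, cfg$gamma * (1 - pt)^(cfg$gamma - 1) * pt * logp_t)
  } else 0
  gfac <- w * (term1 - (1 - pt)^cfg$gamma)
  gfac[!keep] <- 0
  if (n_eff > 0) gfac <- gfac / n_eff
  dz <- -p * rep(gfac, each = K)
  dz[cbind(lab + 1L, seq_len(m))] <- dz[cbind(lab + 1L, seq_len(m))] + gfac
  fw <- cfg$focal_weight %||% 1
  nel <- length(ndvi)
  diffs <- ndvi - ndvi_true
  mse <- mean(diffs^2)
  dnd <- cfg$ndvi_weight * 2 * diffs / nel
  list(total = fw * focal + cfg$ndvi_weight * mse, focal = focal,
       mse = mse, dlogits = array(fw * dz, dim(logits)), dndvi = dnd)
}
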