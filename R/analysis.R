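# Post-hoc analyses: full-scene map inference, planted-area statistics,
# temporal class-activation profiles, and predicted-vs-observed NDVI curves.

#' Classify a full scene and mosaic the result
#'
#' Cuts the scene into patches (partial edge tiles are discarded, as in
#' dataset construction), predicts per-pixel labels patch by patch, and
#' mosaics them back into a label raster. Pixels not covered by a whole tile
#' get the `nodata` value.
#'
#' @param fit A `safpn_fit` or [safpn_model()].
#' @param scene Array `(T, B, Hs, Ws)`.
#' @param dates Acquisition dates of the scene.
#' @param nodata Fill value for uncovered edge pixels.
#' @param batch Inference batch size.
#' @return Integer `Hs x Ws` label raster.
#' @export
predict_map <- function(fit, scene, dates = NULL, nodata = 255L, batch = 16L) {
  model <- if (inherits(fit, "safpn_fit")) fit$model else fit
  cf <- model$config
  d <- dim(scene)
  if (length(d) != 4) stop("scene must be a (T, B, Hs, Ws) array")
  if (d[1] != cf$n_dates || d[2] != cf$n_bands) {
    stop(sprintf("scene has T=%d, B=%d; checkpoint expects T=%d, B=%d",
                 d[1], d[2], cf$n_dates, cf$n_bands))
  }
  ps <- cf$patch_size
  patches <- grid_partition(scene, NULL, ps, dates = dates)
  te <- patches_to_tensors(patches, cf, need_ndvi = FALSE)
  pl <- predict_labels_internal(model, te, batch)
  out <- matrix(as.integer(nodata), d[3], d[4])
  nr <- d[3] %/% ps; nc <- d[4] %/% ps
  m <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- (i - 1L) * ps + seq_len(ps)
      cs <- (j - 1L) * ps + seq_len(ps)
      out[rs, cs] <- matrix(pl[, m], ps, ps)
      m <- m + 1L
    }
  }
  out
}

#' Planted-area statistics from pixel counts
#'
#' Each pixel covers `resolution_m^2` square metres; areas are reported in
#' m2 and hectares (1 ha = 10,000 m2), hectares rounded to 2 decimals.
#'
#' @param pixel_counts Non-negative integer vector, optionally named by
#'   class.
#' @param resolution_m Ground resolution in metres/pixel.
#' @return Object of class `area_report`: data frame with columns `class`,
#'   `pixel_count`, `area_m2`, `area_ha`.
#' @export
area_from_counts <- function(pixel_counts, resolution_m = 10) {
  if (any(pixel_counts < 0)) stop("pixel counts must be non-negative")
  stopifnot(resolution_m > 0)
  cls <- names(pixel_counts) %||% as.character(seq_along(pixel_counts) - 1L)
  m2 <- as.numeric(pixel_counts) * resolution_m^2
  out <- data.frame(class = cls, pixel_count = as.numeric(pixel_counts),
                    area_m2 = m2, area_ha = round(m2 / 10000, 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("area_report", class(out))
  out
}

#' Count predicted pixels per class in a label raster
#'
#' @param label_map Integer matrix (e.g. from [predict_map()]).
#' @param n_classes Number of classes; values outside `0..n_classes-1`
#'   (such as the nodata fill) are ignored.
#' @return Named integer vector of per-class pixel counts.
#' @export
class_pixel_counts <- function(label_map, n_classes) {
  v <- as.integer(label_map)
  v <- v[v >= 0L & v < n_classes]
  counts <- tabulate(v + 1L, nbins = n_classes)
  names(counts) <- as.character(0:(n_classes - 1L))
  counts
}

#' Temporal class-activation profile (CAI)
#'
#' Gradient-times-activation attribution along the temporal axis of the
#' shared feature volume that feeds the NDVI regression layer: for each
#' acquisition date, the spatial mean (over the parcel mask) of the inner
#' product between that date's feature activations and the gradient of the
#' class logit with respect to them, mean-centered across dates. Positive
#' values mark dates whose features push the model towards the class,
#' negative values dates that push away.
#'
#' @param fit A `safpn_fit` or [safpn_model()].
#' @param patch A [ts_patch()].
#' @param class_id Class whose evidence is attributed, 0-based.
#' @param mask Logical `H x W` parcel mask; default: pixels labelled
#'   `class_id` (all pixels if none are).
#' @return Object of class `cai_series`: list with `class_id`, `values`
#'   (length T, signed, zero mean), `dates`.
#' @export
extract_cai <- function(fit, patch, class_id, mask = NULL) {
  model <- if (inherits(fit, "safpn_fit")) fit$model else fit
  cf <- model$config
  if (class_id < 0 || class_id >= cf$n_classes) {
    stop(sprintf("class_id must lie in [0, %d)", cf$n_classes))
  }
  H <- cf$patch_size; T <- cf$n_dates; HW <- H * H
  if (is.null(mask)) {
    mask <- patch$labels == class_id
    if (!any(mask)) mask <- matrix(TRUE, H, H)
  }
  if (!any(mask)) stop("empty parcel mask")
  x <- vol_from_reflectance(patch$reflectance)
  fw <- model_forward(model, x, N = 1L, train = FALSE, keep_cache = TRUE)
  zero_grads(model)
  dlog <- array(0, c(cf$n_classes, HW, 1L))
  sel <- which(as.vector(mask))
  dlog[class_id + 1L, sel, 1L] <- 1 / length(sel)
  dnd <- matrix(0, HW * T, 1L)
  bw <- model_backward(model, fw$cache, dlog, dnd, N = 1L, upto = "volume")
  V <- fw$cache$V
  g <- bw$dvolume
  scores <- numeric(T)
  for (t in seq_len(T)) {
    cols <- (t - 1L) * HW + seq_len(HW)
    per_pixel <- colSums(matrix(V[, cols, 1L] * g[, cols, 1L],
                                dim(V)[1], HW))
    scores[t] <- mean(per_pixel[sel])
  }
  structure(list(class_id = as.integer(class_id),
                 values = scores - mean(scores),
                 raw = scores,
                 dates = patch$dates), class = "cai_series")
}

#' @export
print.cai_series <- function(x, ...) {
  cat(sprintf("<cai_series class %d over %d dates; peak at DOY %g>\n",
              x$class_id, length(x$values), x$dates[which.max(x$values)]))
  invisible(x)
}

#' Predicted vs observed NDVI curve over a parcel
#'
#' Spatial mean, per acquisition date, of the NDVI regression-head output
#' and of the NDVI computed from the red/NIR bands, over a parcel mask.
#'
#' @param fit A `safpn_fit` or [safpn_model()].
#' @param patch A [ts_patch()] carrying B4/B8 bands.
#' @param mask Logical `H x W` parcel mask (non-empty).
#' @return Data frame with columns `date`, `predicted`, `observed`.
#' @export
ndvi_curve_comparison <- function(fit, patch, mask) {
  model <- if (inherits(fit, "safpn_fit")) fit$model else fit
  if (!any(mask)) stop("empty parcel mask")
  fw <- safpn_forward(model, patch)
  obs <- ndvi_series(patch)$values
  T <- dim(obs)[1]
  sel <- which(as.vector(mask))
  pred_m <- vapply(seq_len(T), function(t) {
    mean(as.vector(fw$ndvi[t, , ])[sel])
  }, 1)
  obs_m <- vapply(seq_len(T), function(t) {
    mean(as.vector(obs[t, , ])[sel])
  }, 1)
  data.frame(date = patch$dates, predicted = pred_m, observed = obs_m)
}
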