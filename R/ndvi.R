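# NDVI: (NIR - RED) / (NIR + RED), per pixel and per acquisition.

#' Compute NDVI from near-infrared and red reflectance
#'
#' Elementwise `(nir - red) / (nir + red)`. Pixels where `nir + red = 0`
#' (the formula is undefined there) are set to 0; their count is reported
#' with a message so silent saturation does not go unnoticed.
#'
#' @param nir,red Numeric arrays of identical shape with non-negative values.
#' @return Array of the same shape, bounded in \[-1, 1\].
#' @export
compute_ndvi <- function(nir, red) {
  if (!identical(dim(nir) %||% length(nir), dim(red) %||% length(red))) {
    stop("nir and red must have identical shape")
  }
  if (any(nir < 0) || any(red < 0)) {
    stop("reflectance must be non-negative")
  }
  den <- nir + red
  zero <- den == 0
  out <- nir - red
  out[!zero] <- out[!zero] / den[!zero]
  out[zero] <- 0
  if (any(zero)) {
    message(sprintf("compute_ndvi: %d pixel(s) with NIR + RED = 0 set to 0",
                    sum(zero)))
  }
  out
}

#' NDVI time series of a patch
#'
#' Applies [compute_ndvi()] to the B8 (NIR) and B4 (red) bands of every
#' acquisition.
#'
#' @param patch A [ts_patch()].
#' @param band_specs List of [band_spec()] naming the patch's bands; by
#'   default the patch's own `bands` field is used.
#' @return Object of class `ndvi_series`: list with `values` (`T x H x W`)
#'   and `dates`.
#' @export
ndvi_series <- function(patch, band_specs = NULL) {
  stopifnot(inherits(patch, "ts_patch"))
  nm <- if (!is.null(band_specs)) {
    vapply(band_specs, function(s) s$name, "")
  } else patch$bands
  if (is.null(nm)) stop("no band names available; supply band_specs")
  for (need in c("B8", "B4")) {
    if (!need %in% nm) {
      stop(sprintf("band %s not present; available: %s", need,
                   paste(nm, collapse = ", ")))
    }
  }
  i_nir <- match("B8", nm); i_red <- match("B4", nm)
  d <- dim(patch$reflectance)
  vals <- array(0, c(d[1], d[3], d[4]))
  for (t in seq_len(d[1])) {
    vals[t, , ] <- compute_ndvi(matrix(patch$reflectance[t, i_nir, , ], d[3], d[4]),
                                matrix(patch$reflectance[t, i_red, , ], d[3], d[4]))
  }
  structure(list(values = vals, dates = patch$dates), class = "ndvi_series")
}
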