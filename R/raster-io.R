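# Raster time-series input/output: band handling, TIFF scenes, patch
# directories, grid partitioning and leakage-free patch-level splits.
#
# No GDAL binding is used: pixels travel through plain (Geo)TIFF via the
# `tiff` package, and geo metadata (affine transform + CRS) rides in a JSON
# sidecar `<file>.aux.json` written next to each raster.

#' Describe a spectral band
#'
#' @param name Band identifier, e.g. `"B2"`.
#' @param native_resolution Native ground resolution in metres/pixel.
#' @param index 0-based position of the band along the band axis.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, native_resolution, index) {
  stopifnot(is.character(name), length(name) == 1, native_resolution > 0,
            index >= 0)
  structure(list(name = name, native_resolution = native_resolution,
                 index = as.integer(index)), class = "band_spec")
}

#' Default band set: the four 10 m Sentinel-2 bands
#'
#' B2 (blue), B3 (green), B4 (red), B8 (near-infrared), all at 10 m.
#'
#' @return List of [band_spec()] objects.
#' @export
default_band_specs <- function() {
  nm <- c("B2", "B3", "B4", "B8")
  lapply(seq_along(nm), function(i) band_spec(nm[i], 10, i - 1L))
}

# a spec list passed to load_scene may be any subset of a file's bands, so
# only uniqueness is enforced here; contiguity from 0 is the invariant of a
# complete band-set definition
validate_band_specs <- function(specs) {
  idx <- vapply(specs, function(s) s$index, 1L)
  if (anyDuplicated(idx)) {
    stop("band indices must be unique")
  }
  invisible(specs)
}

geo_sidecar_path <- function(path) paste0(path, ".aux.json")

read_geo_sidecar <- function(path) {
  sc <- geo_sidecar_path(path)
  if (file.exists(sc)) jsonlite::fromJSON(sc) else NULL
}

write_geo_sidecar <- function(path, geo) {
  if (is.null(geo)) return(invisible(NULL))
  jsonlite::write_json(geo, geo_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

# read a (possibly multi-page / multi-channel) TIFF as a list of 2-D
# matrices. Integer pages are returned at their raw integer values, float
# pages as stored: the scaled and the as-is readings are compared per page
# to tell the two sample formats apart (the TIFF reader rescales integer
# samples to [0,1] and cannot return float samples "as is").
read_tiff_bands <- function(path) {
  sc <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  ai <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(sc)) { sc <- list(sc); ai <- list(ai) }
  out <- list()
  for (p in seq_along(sc)) {
    pg <- sc[[p]]
    bits <- attr(pg, "bits.per.sample") %||% 32L
    vmax <- 2^bits - 1
    # 8/16-bit samples are integers rescaled to [0,1] by the reader;
    # 32-bit samples are floats returned as stored
    is_int <- bits <= 16L && max(abs(ai[[p]] - pg * vmax)) < 0.5
    vals <- if (is_int) round(pg * vmax) else pg
    attributes(vals) <- list(dim = dim(pg))
    if (length(dim(vals)) == 3) {
      for (ch in seq_len(dim(vals)[3])) out[[length(out) + 1L]] <- vals[, , ch]
    } else {
      out[[length(out) + 1L]] <- vals
    }
  }
  out
}

#' Load a multispectral scene from a raster file
#'
#' Reads a single- or multi-band TIFF (plain or GeoTIFF pixels) and returns
#' the requested bands in `band_specs` order, normalized to reflectance in
#' \[0, 1\]. Integer-scaled products (e.g. 0--10000) are divided by `scale`;
#' with `scale = NULL` the scale is inferred (values above 1.5 imply the
#' 0--10000 convention).
#'
#' @param path Raster file.
#' @param band_specs List of [band_spec()]; the `index` field selects the
#'   page/channel in the file.
#' @param scale Reflectance divisor, or `NULL` to auto-detect.
#' @param fill_value Optional value substituted for non-finite pixels; with
#'   `NULL`, non-finite pixels are an error.
#' @return List with `bands` (named list of H x W matrices, in `band_specs`
#'   order) and `geo` (transform/CRS list from the JSON sidecar, or `NULL`).
#' @export
load_scene <- function(path, band_specs = default_band_specs(), scale = NULL,
                       fill_value = NULL) {
  if (!file.exists(path)) stop(sprintf("no such raster file: %s", path))
  validate_band_specs(band_specs)
  avail <- read_tiff_bands(path)
  out <- list()
  for (sp in band_specs) {
    if (sp$index + 1L > length(avail)) {
      stop(sprintf("band %s (index %d) not present; file has %d band(s): indices 0..%d",
                   sp$name, sp$index, length(avail), length(avail) - 1L))
    }
    b <- avail[[sp$index + 1L]]
    storage.mode(b) <- "double"
    if (any(!is.finite(b))) {
      if (is.null(fill_value)) {
        stop(sprintf("non-finite pixels in band %s and no fill_value configured",
                     sp$name))
      }
      b[!is.finite(b)] <- fill_value
    }
    out[[sp$name]] <- b
  }
  mx <- max(vapply(out, max, 1), 0)
  sc <- scale %||% (if (mx > 1.5) 10000 else 1)
  if (sc != 1) out <- lapply(out, function(b) b / sc)
  list(bands = out, geo = read_geo_sidecar(path))
}

#' Resample a band to a common grid
#'
#' Nearest-neighbour (default) or bilinear resampling between grids whose
#' resolutions are integer multiples of one another.
#'
#' @param band 2-D numeric matrix.
#' @param native_res Resolution of `band`, metres/pixel.
#' @param target_res Target resolution, metres/pixel.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Matrix on the target grid.
#' @export
resample_to_common_grid <- function(band, native_res, target_res,
                                    method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(band), native_res > 0, target_res > 0)
  if (native_res == target_res) return(band)
  if (native_res > target_res) {
    f <- native_res / target_res
    if (abs(f - round(f)) > 1e-9) {
      stop(sprintf("resolution ratio %g is not an integer", f))
    }
    f <- as.integer(round(f))
    if (method == "nearest") {
      return(band[rep(seq_len(nrow(band)), each = f),
                  rep(seq_len(ncol(band)), each = f), drop = FALSE])
    }
    return(bilinear_upsample(band, f))
  }
  f <- target_res / native_res
  if (abs(f - round(f)) > 1e-9) {
    stop(sprintf("resolution ratio %g is not an integer", f))
  }
  f <- as.integer(round(f))
  if (nrow(band) %% f != 0 || ncol(band) %% f != 0) {
    stop("band dimensions are not divisible by the aggregation factor")
  }
  if (method == "nearest") {
    return(band[seq(1L, nrow(band), by = f), seq(1L, ncol(band), by = f),
                drop = FALSE])
  }
  # block mean aggregation
  H <- nrow(band) %/% f; W <- ncol(band) %/% f
  a <- array(band, c(f, H, f * W))
  m1 <- apply(array(colMeans(a), c(H, f, W)), c(1, 3), mean)
  matrix(m1, H, W)
}

bilinear_upsample <- function(band, f) {
  H <- nrow(band); W <- ncol(band)
  # output pixel centers mapped into input index space, edges replicated
  pos <- function(n) pmin(pmax(((seq_len(n * f) - 0.5) / f) + 0.5 - 0.5, 1), n)
  ry <- pos(H); rx <- pos(W)
  y0 <- pmin(floor(ry), H - 1L); x0 <- pmin(floor(rx), W - 1L)
  wy <- ry - y0; wx <- rx - x0
  b00 <- band[y0, x0, drop = FALSE]; b10 <- band[y0 + 1, x0, drop = FALSE]
  b01 <- band[y0, x0 + 1, drop = FALSE]; b11 <- band[y0 + 1, x0 + 1, drop = FALSE]
  (1 - wy) * ((1 - wx[col(b00)]) * b00 + wx[col(b00)] * b01) +
    wy * ((1 - wx[col(b00)]) * b10 + wx[col(b00)] * b11)
}

## ---- patches ----------------------------------------------------------------

#' Construct a time-series patch
#'
#' @param reflectance Array `(T, B, H, W)`, reflectance in \[0, 1\] (values
#'   above 1.5 are treated as 0--10000 scaled and normalized).
#' @param dates Strictly increasing numeric acquisition dates (day of year).
#' @param labels Integer `H x W` matrix, values in `0..n_classes-1`.
#' @param patch_id Unique identifier string.
#' @param resolution_m Metres/pixel of the common grid.
#' @param geo Optional list with affine `transform` and `crs`.
#' @param bands Optional character vector of band names (length B).
#' @param ndvi Optional `(T, H, W)` array of the noise-free/observed NDVI
#'   field (attached by the synthetic generator).
#' @return Object of class `ts_patch`.
#' @export
ts_patch <- function(reflectance, dates, labels, patch_id,
                     resolution_m = 10, geo = NULL, bands = NULL, ndvi = NULL) {
  d <- dim(reflectance)
  if (length(d) != 4) stop("reflectance must be a (T, B, H, W) array")
  if (length(dates) != d[1]) stop("length(dates) must equal T")
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing")
  if (!identical(as.integer(dim(labels)), as.integer(d[3:4]))) {
    stop("labels shape must equal (H, W)")
  }
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  if (max(reflectance) > 1.5) reflectance <- reflectance / 10000
  structure(list(reflectance = reflectance, dates = as.numeric(dates),
                 labels = matrix(as.integer(labels), d[3], d[4]),
                 patch_id = as.character(patch_id),
                 resolution_m = resolution_m, geo = geo,
                 bands = bands, ndvi = ndvi),
            class = "ts_patch")
}

#' @export
print.ts_patch <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<ts_patch %s: T=%d B=%d %dx%d px @ %g m, %d classes present>\n",
              x$patch_id, d[1], d[2], d[3], d[4], x$resolution_m,
              length(unique(as.integer(x$labels)))))
  invisible(x)
}

#' Cut a scene into regular non-overlapping patches
#'
#' Tiles are scanned row-major from the top-left origin; partial tiles at the
#' right/bottom edges are discarded. Patch ids encode the (row, col) tile
#' indices as `r<row>_c<col>` (0-based).
#'
#' @param scene Array `(T, B, Hs, Ws)`.
#' @param labels Integer `Hs x Ws` matrix, or `NULL` (labels filled with 0).
#' @param patch_size Tile side in pixels.
#' @param dates Acquisition dates (length T).
#' @param resolution_m Metres/pixel.
#' @param geo Optional geo metadata carried to every patch.
#' @param bands Optional band names.
#' @return List of [ts_patch()] objects, length
#'   `floor(Hs/patch_size) * floor(Ws/patch_size)`.
#' @export
grid_partition <- function(scene, labels, patch_size, dates = NULL,
                           resolution_m = 10, geo = NULL, bands = NULL) {
  d <- dim(scene)
  if (length(d) != 4) stop("scene must be a (T, B, Hs, Ws) array")
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1")
  if (patch_size > d[3] && patch_size > d[4]) {
    stop(sprintf("patch_size %d exceeds both scene dimensions (%d x %d)",
                 patch_size, d[3], d[4]))
  }
  if (is.null(labels)) labels <- matrix(0L, d[3], d[4])
  if (!identical(as.integer(dim(labels)), as.integer(d[3:4]))) {
    stop("labels must be spatially aligned with the scene")
  }
  if (is.null(dates)) dates <- seq_len(d[1])
  nr <- d[3] %/% patch_size
  nc <- d[4] %/% patch_size
  out <- vector("list", nr * nc)
  m <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- (i - 1L) * patch_size + seq_len(patch_size)
      cs <- (j - 1L) * patch_size + seq_len(patch_size)
      out[[m]] <- ts_patch(scene[, , rs, cs, drop = FALSE], dates,
                           labels[rs, cs], sprintf("r%d_c%d", i - 1L, j - 1L),
                           resolution_m = resolution_m, geo = geo,
                           bands = bands)
      m <- m + 1L
    }
  }
  out
}

#' Split patch ids into train/validation/test subsets
#'
#' Ids are shuffled by the seeded generator; the first
#' `floor(N*r1/sum(r))` go to the first subset, the next
#' `floor(N*r2/sum(r))` to the second, and all remaining ids to the third.
#' Splitting at patch level prevents pixels of one location leaking across
#' subsets.
#'
#' @param patch_ids Character vector of unique ids.
#' @param ratios Length-3 non-negative weights, e.g. `c(6, 2, 2)`.
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @return A `data.frame` with columns `patch_id` and `subset`
#'   (train/val/test), with the ratios and seed as attributes.
#' @export
split_dataset <- function(patch_ids, ratios = c(6, 2, 2), seed = 1L) {
  if (length(patch_ids) == 0) stop("patch_ids is empty")
  if (anyDuplicated(patch_ids)) stop("patch_ids must be unique")
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  N <- length(patch_ids)
  set.seed(as.integer(seed))
  ord <- sample(N)
  n1 <- floor(N * ratios[1] / sum(ratios))
  n2 <- floor(N * ratios[2] / sum(ratios))
  subset <- rep("test", N)
  subset[ord[seq_len(n1)]] <- "train"
  if (n2 > 0) subset[ord[n1 + seq_len(n2)]] <- "val"
  out <- data.frame(patch_id = as.character(patch_ids),
                    subset = factor(subset, levels = c("train", "val", "test")),
                    stringsAsFactors = FALSE)
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- as.integer(seed)
  out
}

## ---- on-disk patch layout ---------------------------------------------------
# <dir>/<patch_id>/x.tif   multi-page float TIFF, page (t-1)*B + b
# <dir>/<patch_id>/y.tif   8-bit label raster
# <dir>/<patch_id>/dates.txt, meta.json

#' Write a patch directory
#'
#' @param patch A [ts_patch()].
#' @param dir Parent directory; the patch is written to `<dir>/<patch_id>/`.
#' @return The patch directory path, invisibly.
#' @export
write_patch <- function(patch, dir) {
  stopifnot(inherits(patch, "ts_patch"))
  pd <- file.path(dir, patch$patch_id)
  ok <- dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(pd)) stop(sprintf("cannot create patch directory %s", pd))
  d <- dim(patch$reflectance)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) {
    for (b in seq_len(d[2])) {
      pages[[(t - 1L) * d[2] + b]] <- matrix(patch$reflectance[t, b, , ],
                                             d[3], d[4])
    }
  }
  res <- try(tiff::writeTIFF(pages, file.path(pd, "x.tif"),
                             bits.per.sample = 32L), silent = TRUE)
  if (inherits(res, "try-error")) {
    stop(sprintf("failed writing %s: %s", file.path(pd, "x.tif"),
                 attr(res, "condition")$message))
  }
  tiff::writeTIFF(patch$labels / 255, file.path(pd, "y.tif"),
                  bits.per.sample = 8L)
  writeLines(format(patch$dates, scientific = FALSE),
             file.path(pd, "dates.txt"))
  meta <- list(patch_id = patch$patch_id, resolution_m = patch$resolution_m,
               n_dates = d[1], n_bands = d[2], bands = patch$bands,
               geo = patch$geo)
  jsonlite::write_json(meta, file.path(pd, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(patch$ndvi)) {
    npages <- lapply(seq_len(d[1]), function(t) {
      (matrix(patch$ndvi[t, , ], d[3], d[4]) + 1) / 2
    })
    tiff::writeTIFF(npages, file.path(pd, "ndvi.tif"), bits.per.sample = 32L)
  }
  invisible(pd)
}

#' Read a patch directory written by [write_patch()]
#'
#' @param pd Patch directory.
#' @return A [ts_patch()].
#' @export
read_patch <- function(pd) {
  meta <- jsonlite::fromJSON(file.path(pd, "meta.json"))
  pages <- read_tiff_bands(file.path(pd, "x.tif"))
  T <- meta$n_dates; B <- meta$n_bands
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  refl <- array(0, c(T, B, H, W))
  for (t in seq_len(T)) {
    for (b in seq_len(B)) refl[t, b, , ] <- pages[[(t - 1L) * B + b]]
  }
  lab <- round(tiff::readTIFF(file.path(pd, "y.tif")) * 255)
  dates <- as.numeric(readLines(file.path(pd, "dates.txt")))
  ndvi <- NULL
  if (file.exists(file.path(pd, "ndvi.tif"))) {
    np <- read_tiff_bands(file.path(pd, "ndvi.tif"))
    ndvi <- array(0, c(T, H, W))
    for (t in seq_len(T)) ndvi[t, , ] <- np[[t]] * 2 - 1
  }
  geo <- meta$geo
  if (is.null(geo) || length(geo) == 0) geo <- NULL
  ts_patch(refl, dates, lab, meta$patch_id, resolution_m = meta$resolution_m,
           geo = geo, bands = unlist(meta$bands), ndvi = ndvi)
}

#' Write a dataset manifest
#'
#' Plain-text tab-separated table with columns `patch_id`, `subset`, `path`.
#'
#' @param manifest Data frame with those columns.
#' @param path Destination file.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("patch_id", "subset", "path") %in% names(manifest)))
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest file written by [write_manifest()].
#' @return Data frame with `patch_id`, `subset`, `path`.
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character")
}

#' Load the patches of one manifest subset
#'
#' @param manifest Manifest data frame (or path to one).
#' @param subset One of `"train"`, `"val"`, `"test"`, or `NULL` for all.
#' @param root Directory that relative manifest paths are resolved against.
#' @return List of [ts_patch()] objects.
#' @export
load_patches <- function(manifest, subset = NULL, root = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- if (is.null(subset)) seq_len(nrow(manifest)) else
    which(manifest$subset == subset)
  lapply(rows, function(i) {
    p <- manifest$path[i]
    if (!dir.exists(p)) p <- file.path(root, p)
    read_patch(p)
  })
}
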