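# Synthetic labeled scenes: parcel-structured label maps with class-specific
# double-logistic NDVI phenologies, rendered into red/NIR (and companion)
# reflectance bands so that the NDVI formula inverts the construction
# exactly. Emulates the statistical structure of an irrigated multi-crop
# plain: a few dominant crops, several rare ones, and an inter-row
# mixed-cropping confusion mode where two crops alternate by pixel row
# within one parcel.

#' Phenology parameters for one class
#'
#' The seasonal NDVI trajectory is the standard double-logistic model:
#' `base + (peak - base) * (sigma(rate*(d - green_up)) - sigma(rate*(d - senescence)))`
#' with `sigma` the logistic function and `d` the day of year.
#'
#' @param class_id Integer class id (0 = "others").
#' @param ndvi_base Background NDVI level, in \[-1, 1\].
#' @param ndvi_peak Seasonal maximum NDVI, greater than `ndvi_base`.
#' @param green_up_day,senescence_day Days of year of the two transitions.
#' @param transition_rate Slope of each logistic transition (1/day).
#' @param noise_sd Per-pixel per-date Gaussian noise added to the NDVI.
#' @return Object of class `crop_phenology`.
#' @export
crop_phenology <- function(class_id, ndvi_base, ndvi_peak, green_up_day,
                           senescence_day, transition_rate, noise_sd = 0.05) {
  stopifnot(ndvi_base >= -1, ndvi_base < ndvi_peak, ndvi_peak <= 1,
            green_up_day < senescence_day, transition_rate > 0, noise_sd >= 0)
  structure(list(class_id = as.integer(class_id), ndvi_base = ndvi_base,
                 ndvi_peak = ndvi_peak, green_up_day = green_up_day,
                 senescence_day = senescence_day,
                 transition_rate = transition_rate, noise_sd = noise_sd),
            class = "crop_phenology")
}

#' Evaluate a phenology curve
#'
#' @param params A [crop_phenology()].
#' @param dates Numeric days of year.
#' @return Numeric NDVI trajectory, same length as `dates`, in \[-1, 1\].
#' @export
phenology_curve <- function(params, dates) {
  stopifnot(inherits(params, "crop_phenology"))
  if (length(dates) == 0) stop("dates is empty")
  s1 <- stats::plogis(params$transition_rate * (dates - params$green_up_day))
  s2 <- stats::plogis(params$transition_rate * (dates - params$senescence_day))
  params$ndvi_base + (params$ndvi_peak - params$ndvi_base) * (s1 - s2)
}

#' Scene recipe for the synthetic generator
#'
#' @param class_params List of [crop_phenology()], one per class, ordered by
#'   class id starting at 0.
#' @param class_proportions Non-negative weights summing to 1; parcels draw
#'   their class from this distribution (strong imbalance is the default
#'   regime).
#' @param parcel_min,parcel_max Parcel side lengths in pixels.
#' @param dates Strictly increasing acquisition days of year.
#' @param mixed_pairs Optional list of length-2 integer vectors
#'   `c(dominant, companion)`: parcels of the dominant class may be rendered
#'   as inter-row mixed cropping, alternating the two classes by pixel row
#'   (labels stay at the dominant class).
#' @param mixed_fraction Probability that an eligible parcel is mixed.
#' @param bands Band names rendered, must contain `"B4"` and `"B8"`.
#' @param ndvi_scale_k Overall reflectance magnitude `k` in the inversion
#'   `NIR = k(1+v)/2`, `RED = k(1-v)/2` for NDVI value `v`.
#' @param resolution_m Ground resolution, metres/pixel.
#' @param seed Base seed for rendering.
#' @return Object of class `scene_recipe`.
#' @export
scene_recipe <- function(class_params, class_proportions,
                         parcel_min = 6L, parcel_max = 12L,
                         dates = seq(95, 285, by = 10),
                         mixed_pairs = NULL, mixed_fraction = 0.1,
                         bands = c("B2", "B3", "B4", "B8"),
                         ndvi_scale_k = 0.6, resolution_m = 10, seed = 1L) {
  n <- length(class_params)
  stopifnot(n >= 1, length(class_proportions) == n,
            all(class_proportions >= 0),
            abs(sum(class_proportions) - 1) < 1e-9,
            parcel_min >= 1, parcel_max >= parcel_min,
            all(diff(dates) > 0),
            all(c("B4", "B8") %in% bands),
            ndvi_scale_k > 0, ndvi_scale_k <= 1)
  ids <- vapply(class_params, function(p) p$class_id, 1L)
  if (!identical(ids, seq_len(n) - 1L)) {
    stop("class_params must be ordered by class_id 0..n-1")
  }
  if (!is.null(mixed_pairs)) {
    for (pr in mixed_pairs) {
      stopifnot(length(pr) == 2, all(pr %in% (seq_len(n) - 1L)))
    }
  }
  structure(list(n_classes = n, class_params = class_params,
                 class_proportions = class_proportions,
                 parcel_min = as.integer(parcel_min),
                 parcel_max = as.integer(parcel_max),
                 dates = as.numeric(dates), mixed_pairs = mixed_pairs,
                 mixed_fraction = mixed_fraction, bands = bands,
                 ndvi_scale_k = ndvi_scale_k, resolution_m = resolution_m,
                 seed = as.integer(seed)), class = "scene_recipe")
}

#' Default eight-class recipe (Talhu-style regime)
#'
#' Eight classes -- 0 others, 1 maize, 2 sunflower, 3 wheat, 4 honeydew
#' melon, 5 tomato, 6 zucchini, 7 sugar beet -- with distinct double-logistic
#' phenologies over 20 acquisitions (DOY 95..285), dominant
#' sunflower/others/maize, rare sugar beet and melon, and inter-row mixed
#' cropping of (sugar beet, zucchini) and (honeydew melon, tomato).
#'
#' @param noise_sd Per-pixel NDVI noise standard deviation for every class.
#' @param seed Base seed.
#' @return A [scene_recipe()].
#' @export
talhu_recipe <- function(noise_sd = 0.05, seed = 1L) {
  cp <- list(
    crop_phenology(0L, 0.10, 0.25, 130, 250, 0.05, noise_sd),  # others
    crop_phenology(1L, 0.14, 0.88, 155, 270, 0.12, noise_sd),  # maize
    crop_phenology(2L, 0.15, 0.80, 175, 265, 0.12, noise_sd),  # sunflower
    crop_phenology(3L, 0.16, 0.75, 105, 195, 0.12, noise_sd),  # wheat
    crop_phenology(4L, 0.13, 0.60, 160, 235, 0.12, noise_sd),  # honeydew melon
    crop_phenology(5L, 0.14, 0.70, 150, 255, 0.10, noise_sd),  # tomato
    crop_phenology(6L, 0.13, 0.65, 170, 245, 0.14, noise_sd),  # zucchini
    crop_phenology(7L, 0.12, 0.85, 165, 290, 0.09, noise_sd))  # sugar beet
  scene_recipe(cp,
               class_proportions = c(0.30, 0.12, 0.25, 0.07, 0.05, 0.10,
                                     0.08, 0.03),
               mixed_pairs = list(c(7L, 6L), c(4L, 5L)),
               seed = seed)
}

#' Class names of the default recipe
#' @return Character vector of length 8, indexed by class id + 1.
#' @export
talhu_class_names <- function() {
  c("others", "maize", "sunflower", "wheat", "honeydew melon", "tomato",
    "zucchini", "sugar beet")
}

# tessellate a patch_size square into axis-aligned rectangular parcels
parcel_tessellation <- function(patch_size, pmin, pmax) {
  cuts <- function() {
    b <- integer(0); pos <- 0L
    while (pos < patch_size) {
      w <- sample(pmin:pmax, 1L)
      pos <- min(pos + w, patch_size)
      b <- c(b, pos)
    }
    b
  }
  rows <- cuts(); cols <- cuts()
  list(rows = rows, cols = cols)
}

#' Render one synthetic patch
#'
#' The label map is a tessellation of axis-aligned parcels with classes drawn
#' from the recipe's proportions. Reflectance is built by inverting the NDVI
#' formula: for per-pixel noisy NDVI `v`, `B8 = k(1+v)/2` and
#' `B4 = k(1-v)/2`, so computing NDVI from the rendered bands reproduces `v`
#' exactly; other bands carry correlated noise. Mixed-cropping parcels
#' alternate the paired classes by pixel row with the label set to the
#' dominant class.
#'
#' @param recipe A [scene_recipe()].
#' @param patch_size Patch side, pixels; at least `parcel_min`.
#' @param seed Seed for this patch (defaults to the recipe seed).
#' @param patch_id Identifier for the returned patch.
#' @return A [ts_patch()] with the noisy NDVI field attached as `$ndvi`.
#' @export
render_patch <- function(recipe, patch_size = 24L, seed = recipe$seed,
                         patch_id = "synthetic") {
  stopifnot(inherits(recipe, "scene_recipe"))
  patch_size <- as.integer(patch_size)
  if (patch_size < recipe$parcel_min) {
    stop(sprintf("patch_size %d is smaller than parcel_min %d", patch_size,
                 recipe$parcel_min))
  }
  set.seed(as.integer(seed))
  T <- length(recipe$dates)
  H <- patch_size; W <- patch_size
  tes <- parcel_tessellation(patch_size, recipe$parcel_min, recipe$parcel_max)
  labels <- matrix(0L, H, W)
  # per-pixel class used for the spectral rendering (differs from labels on
  # the alternate rows of mixed parcels)
  render_class <- matrix(0L, H, W)
  r0 <- 0L
  dominant <- vapply(recipe$mixed_pairs %||% list(), function(p) p[1], 1L)
  for (re in tes$rows) {
    c0 <- 0L
    for (ce in tes$cols) {
      rs <- (r0 + 1L):re; cs <- (c0 + 1L):ce
      cl <- sample(recipe$n_classes, 1L, prob = recipe$class_proportions) - 1L
      labels[rs, cs] <- cl
      render_class[rs, cs] <- cl
      if (cl %in% dominant && stats::runif(1) < recipe$mixed_fraction) {
        pair <- recipe$mixed_pairs[[match(cl, dominant)]]
        alt <- rs[seq_along(rs) %% 2L == 0L]
        render_class[alt, cs] <- pair[2]
      }
      c0 <- ce
    }
    r0 <- re
  }
  curves <- vapply(recipe$class_params, phenology_curve,
                   numeric(T), dates = recipe$dates)   # T x n_classes
  ndvi <- array(0, c(T, H, W))
  for (t in seq_len(T)) {
    base <- matrix(curves[t, render_class + 1L], H, W)
    sdv <- matrix(vapply(recipe$class_params, function(p) p$noise_sd,
                         1)[render_class + 1L], H, W)
    ndvi[t, , ] <- pmin(pmax(base + stats::rnorm(H * W) * sdv, -1), 1)
  }
  k <- recipe$ndvi_scale_k
  B <- length(recipe$bands)
  refl <- array(0, c(T, B, H, W))
  i_red <- match("B4", recipe$bands)
  i_nir <- match("B8", recipe$bands)
  for (t in seq_len(T)) {
    v <- ndvi[t, , ]
    red <- k * (1 - v) / 2
    nir <- k * (1 + v) / 2
    refl[t, i_red, , ] <- red
    refl[t, i_nir, , ] <- nir
    for (b in seq_len(B)) {
      if (b %in% c(i_red, i_nir)) next
      co <- 0.4 + 0.2 * (b %% 3)
      refl[t, b, , ] <- pmin(pmax(co * red + 0.05 +
                                    stats::rnorm(H * W, sd = 0.01), 1e-6), 1)
    }
  }
  refl <- pmin(pmax(refl, 1e-6), 1)
  ts_patch(refl, recipe$dates, labels, patch_id,
           resolution_m = recipe$resolution_m, bands = recipe$bands,
           ndvi = ndvi)
}

#' Render a set of patches in memory
#'
#' @param recipe A [scene_recipe()].
#' @param n_patches Number of patches.
#' @param patch_size Patch side, pixels.
#' @param seed Base seed; patch `i` is rendered with a seed derived from it.
#' @return List of [ts_patch()] objects with ids `p0001`, `p0002`, ...
#' @export
render_patch_set <- function(recipe, n_patches, patch_size = 24L, seed = 1L) {
  stopifnot(n_patches >= 1)
  lapply(seq_len(n_patches), function(i) {
    render_patch(recipe, patch_size,
                 seed = (as.integer(seed) + i * 131L) %% 2147483647L,
                 patch_id = sprintf("p%04d", i))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_patches` patches, writes them in the patch-directory layout of
#' [write_patch()], splits them at patch level with [split_dataset()], and
#' writes a manifest.
#'
#' @param recipe A [scene_recipe()].
#' @param n_patches Number of patches (>= 3).
#' @param dir Output directory.
#' @param ratios Split ratios, default 6:2:2.
#' @param seed Seed for rendering and splitting.
#' @param patch_size Patch side, pixels.
#' @return The manifest data frame (invisibly); also written to
#'   `<dir>/manifest.tsv`.
#' @export
make_dataset <- function(recipe, n_patches, dir, ratios = c(6, 2, 2),
                         seed = 1L, patch_size = 24L) {
  if (n_patches < 3) stop("n_patches must be at least 3")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create dataset directory %s", dir))
  patches <- render_patch_set(recipe, n_patches, patch_size, seed)
  ids <- vapply(patches, function(p) p$patch_id, "")
  split <- split_dataset(ids, ratios, seed)
  paths <- vapply(patches, function(p) write_patch(p, dir), "")
  manifest <- data.frame(patch_id = ids,
                         subset = as.character(split$subset[match(ids, split$patch_id)]),
                         path = paths, stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
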