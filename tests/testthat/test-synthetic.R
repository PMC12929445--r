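test_that("phenology curve matches the closed form and its limits", {
  p <- crop_phenology(1L, 0.1, 0.8, 150, 260, 0.15)
  # far before green-up the curve sits at the base level
  expect_equal(phenology_curve(p, c(1, 20, 40)), rep(0.1, 3), tolerance = 1e-6)
  # midway between steep transitions the curve saturates at the peak
  ps <- crop_phenology(1L, 0.1, 0.8, 150, 260, 5)
  expect_equal(phenology_curve(ps, 205), 0.8, tolerance = 1e-6)
  # independent scalar evaluation of the double-logistic form
  expect_equal(phenology_curve(p, 205),
               dl_oracle(0.1, 0.8, 150, 260, 0.15, 205), tolerance = 1e-12)
  expect_error(phenology_curve(p, numeric(0)), "empty")
  expect_error(crop_phenology(1L, 0.5, 0.4, 100, 200, 0.1))
  expect_error(crop_phenology(1L, 0.1, 0.8, 250, 200, 0.1))
})

test_that("rendered patches are seeded, bounded, and invert through NDVI", {
  rec <- tiny_recipe()
  a <- render_patch(rec, 12, seed = 5)
  b <- render_patch(rec, 12, seed = 5)
  expect_identical(a, b)
  c2 <- render_patch(rec, 12, seed = 6)
  expect_false(identical(a$labels, c2$labels) && identical(a$ndvi, c2$ndvi))

  expect_true(all(a$ndvi >= -1 & a$ndvi <= 1))
  expect_true(all(a$reflectance > 0 & a$reflectance <= 1))

  # the NDVI formula applied to the rendered red/NIR bands recovers the
  # stored noisy NDVI field (construction inverted)
  nv <- ndvi_series(a)$values
  expect_equal(nv, a$ndvi, tolerance = 1e-6)

  # degenerate proportions give a constant label map
  one <- scene_recipe(rec$class_params, c(0, 1, 0), parcel_min = 4L,
                      parcel_max = 6L, dates = rec$dates)
  pc <- render_patch(one, 12, seed = 2)
  expect_true(all(pc$labels == 1L))

  expect_error(render_patch(rec, 3), "parcel_min")
})

test_that("class pixel frequencies follow the recipe proportions", {
  rec <- tiny_recipe(seed = 2)
  pats <- render_patch_set(rec, 200, 12, seed = 77)
  counts <- table(factor(unlist(lapply(pats, function(p) p$labels)),
                         levels = 0:2))
  tot <- sum(counts)
  # parcels are drawn multinomially; parcel-level correlation inflates the
  # variance, so allow 3 standard errors at the effective (parcel) sample size
  n_parcels_approx <- 200 * (12 / 5)^2
  for (k in 1:3) {
    p <- rec$class_proportions[k]
    se <- sqrt(p * (1 - p) / n_parcels_approx)
    expect_lt(abs(counts[k] / tot - p), 3 * se + 0.02)
  }
})

test_that("noise-free patches are separable by nearest-centroid NDVI", {
  rec <- talhu_recipe(noise_sd = 0, seed = 5)
  rec$mixed_pairs <- NULL   # the confusion mode is off for this control
  for (seed in c(99, 100)) {
    p <- render_patch(rec, 24, seed = seed)
    curves <- sapply(rec$class_params, phenology_curve, dates = rec$dates)
    nv <- ndvi_series(p)$values
    err <- 0L
    for (h in 1:24) {
      for (w in 1:24) {
        d2 <- colSums((curves - nv[, h, w])^2)
        if (which.min(d2) - 1L != p$labels[h, w]) err <- err + 1L
      }
    }
    expect_equal(err, 0L)
  }
})

test_that("mixed-cropping parcels alternate spectra by row under one label", {
  rec <- tiny_recipe(noise_sd = 0)
  rec$mixed_pairs <- list(c(1L, 2L))
  rec$mixed_fraction <- 1
  found <- FALSE
  curves <- sapply(rec$class_params, phenology_curve, dates = rec$dates)
  for (seed in 1:10) {
    p <- render_patch(rec, 12, seed = seed)
    cols1 <- which(apply(p$labels == 1L, 2, any))
    for (w in cols1) {
      rows <- which(p$labels[, w] == 1L)
      if (length(rows) < 2) next
      tr <- vapply(rows, function(h) {
        which.min(colSums((curves - p$ndvi[, h, w])^2)) - 1L
      }, 1L)
      if (any(tr == 2L) && any(tr == 1L)) found <- TRUE
    }
    if (found) break
  }
  expect_true(found)
})

test_that("make_dataset writes a reloadable split dataset", {
  td <- withr::local_tempdir()
  mf <- make_dataset(tiny_recipe(), 10, td, ratios = c(6, 2, 2), seed = 3,
                     patch_size = 12)
  expect_equal(nrow(mf), 10)
  expect_equal(as.integer(table(factor(mf$subset,
                                       c("train", "val", "test")))),
               c(6L, 2L, 2L))
  expect_true(file.exists(file.path(td, "manifest.tsv")))
  pats <- load_patches(file.path(td, "manifest.tsv"), "val")
  expect_length(pats, 2)
  for (p in pats) {
    expect_s3_class(p, "ts_patch")
    expect_true(all(p$reflectance > 0 & p$reflectance <= 1))
    expect_true(all(diff(p$dates) > 0))
  }
  expect_error(make_dataset(tiny_recipe(), 2, td), "at least 3")
})
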