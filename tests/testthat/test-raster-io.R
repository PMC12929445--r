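test_that("scene loading round-trips written bands and applies scaling", {
  td <- withr::local_tempdir()
  f <- file.path(td, "scene.tif")
  set.seed(3)
  b1 <- matrix(runif(16), 4, 4)
  b2 <- matrix(runif(16), 4, 4)
  tiff::writeTIFF(list(b1, b2), f, bits.per.sample = 32L)
  specs <- list(band_spec("B4", 10, 0L), band_spec("B8", 10, 1L))
  sc <- load_scene(f, specs)
  expect_equal(sc$bands$B4, b1, tolerance = 1e-6)
  expect_equal(sc$bands$B8, b2, tolerance = 1e-6)
  expect_null(sc$geo)

  # integer 0-10000 dialect normalized on read
  fi <- file.path(td, "int.tif")
  vi <- matrix(c(0, 5000, 10000, 5000), 2, 2)
  tiff::writeTIFF(vi / 65535, fi, bits.per.sample = 16L)
  sci <- load_scene(fi, list(band_spec("B4", 10, 0L)))
  expect_equal(sort(unique(as.vector(sci$bands$B4))), c(0, 0.5, 1))

  # requesting an absent band names it and lists what is available
  expect_error(load_scene(f, list(band_spec("B8A", 20, 5L))),
               "B8A.*indices 0\\.\\.1")
  expect_error(load_scene(file.path(td, "nope.tif"), specs), "no such raster")
})

test_that("geo metadata survives through the JSON sidecar", {
  td <- withr::local_tempdir()
  f <- file.path(td, "geo.tif")
  tiff::writeTIFF(matrix(0.5, 3, 3), f, bits.per.sample = 32L)
  geo <- list(transform = c(600000, 10, 0, 4500000, 0, -10),
              crs = "EPSG:32648")
  safpn:::write_geo_sidecar(f, geo)
  sc <- load_scene(f, list(band_spec("B4", 10, 0L)))
  expect_equal(sc$geo$crs, "EPSG:32648")
  expect_equal(sc$geo$transform, geo$transform)
})

test_that("resampling follows the nearest-neighbour tiling contract", {
  m <- matrix(1:4, 2, 2)
  up <- resample_to_common_grid(m, 20, 10)
  expect_equal(dim(up), c(4L, 4L))
  for (i in 1:2) for (j in 1:2) {
    expect_true(all(up[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] == m[i, j]))
  }
  expect_identical(resample_to_common_grid(m, 10, 10), m)
  one <- matrix(7, 1, 1)
  expect_equal(resample_to_common_grid(one, 60, 10), matrix(7, 6, 6))
  expect_error(resample_to_common_grid(m, 15, 10), "not an integer")
  # downsampling picks the top-left sample of each block
  big <- resample_to_common_grid(matrix(1:16, 4, 4), 10, 20)
  expect_equal(dim(big), c(2L, 2L))
  # bilinear upsample preserves a constant field
  expect_equal(resample_to_common_grid(matrix(2, 3, 3), 20, 10, "bilinear"),
               matrix(2, 6, 6))
})

test_that("grid partitioning tiles row-major and discards edge remainders", {
  mk_scene <- function(Hs, Ws, T = 2, B = 2) {
    array(runif(T * B * Hs * Ws), c(T, B, Hs, Ws))
  }
  set.seed(1)
  s48 <- mk_scene(48, 48)
  p <- grid_partition(s48, NULL, 24)
  expect_length(p, 4)
  expect_equal(p[[1]]$patch_id, "r0_c0")
  expect_equal(p[[2]]$patch_id, "r0_c1")

  s50 <- mk_scene(50, 50)
  expect_length(grid_partition(s50, NULL, 24), 4)

  s24 <- mk_scene(24, 24)
  p1 <- grid_partition(s24, NULL, 24)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$reflectance, s24)

  expect_error(grid_partition(mk_scene(10, 10), NULL, 24), "exceeds")

  # tile count equals the brute-force tiler on random shapes
  brute_tiles <- function(Hs, Ws, ps) {
    n <- 0L
    r <- 1L
    while (r + ps - 1L <= Hs) {
      cc <- 1L
      while (cc + ps - 1L <= Ws) { n <- n + 1L; cc <- cc + ps }
      r <- r + ps
    }
    n
  }
  for (i in 1:10) {
    Hs <- sample(24:60, 1); Ws <- sample(24:60, 1); ps <- sample(5:24, 1)
    sc <- array(0.1, c(1, 1, Hs, Ws))
    expect_length(grid_partition(sc, NULL, ps), brute_tiles(Hs, Ws, ps))
  }
})

test_that("patch-level split reproduces the floor/remainder counts", {
  sp <- split_dataset(sprintf("p%05d", 1:7819), c(6, 2, 2), seed = 4)
  expect_equal(as.integer(table(sp$subset)), c(4691L, 1563L, 1565L))

  sp10 <- split_dataset(as.character(1:10), c(6, 2, 2), seed = 1)
  expect_equal(as.integer(table(sp10$subset)), c(6L, 2L, 2L))
  sp5 <- split_dataset(as.character(1:5), c(6, 2, 2), seed = 1)
  expect_equal(as.integer(table(sp5$subset)), c(3L, 1L, 1L))

  expect_error(split_dataset(character(0)), "empty")
  expect_error(split_dataset(c("a", "a", "b")), "unique")
})

test_that("split is a seeded partition with floor counts for any N and seed", {
  set.seed(99)
  for (i in 1:20) {
    N <- sample(3:400, 1)
    seed <- sample(1e6, 1)
    r <- sample(1:9, 3, replace = TRUE)
    ids <- sprintf("id%04d", seq_len(N))
    sp <- split_dataset(ids, r, seed)
    expect_setequal(sp$patch_id, ids)
    expect_equal(anyDuplicated(sp$patch_id), 0L)
    cnt <- as.integer(table(sp$subset))
    expect_equal(cnt[1], as.integer(floor(N * r[1] / sum(r))))
    expect_equal(cnt[2], as.integer(floor(N * r[2] / sum(r))))
    expect_equal(cnt[3], N - cnt[1] - cnt[2])
    sp2 <- split_dataset(ids, r, seed)
    expect_identical(sp, sp2)
  }
})

test_that("patch directories round-trip reflectance, labels, dates and NDVI", {
  td <- withr::local_tempdir()
  p <- render_patch(tiny_recipe(), 12, seed = 11, patch_id = "rt")
  write_patch(p, td)
  q <- read_patch(file.path(td, "rt"))
  expect_equal(q$reflectance, p$reflectance, tolerance = 1e-6)
  expect_identical(q$labels, p$labels)
  expect_equal(q$dates, p$dates)
  expect_equal(q$ndvi, p$ndvi, tolerance = 1e-6)
  expect_equal(q$bands, p$bands)

  mf <- data.frame(patch_id = "rt", subset = "train",
                   path = file.path(td, "rt"))
  write_manifest(mf, file.path(td, "manifest.tsv"))
  mf2 <- read_manifest(file.path(td, "manifest.tsv"))
  expect_equal(mf2$patch_id, "rt")
  pl <- load_patches(mf2, "train")
  expect_length(pl, 1)
  expect_identical(pl[[1]]$labels, p$labels)
})

test_that("patch constructor enforces its invariants", {
  refl <- array(0.5, c(2, 2, 4, 4))
  expect_error(ts_patch(refl, c(10, 5), matrix(0L, 4, 4), "x"),
               "strictly increasing")
  expect_error(ts_patch(refl, c(5, 10), matrix(0L, 3, 3), "x"), "labels")
  bad <- refl; bad[1] <- NA
  expect_error(ts_patch(bad, c(5, 10), matrix(0L, 4, 4), "x"), "finite")
  # 0-10000 scaled input is normalized
  p <- ts_patch(refl * 10000, c(5, 10), matrix(0L, 4, 4), "x")
  expect_equal(max(p$reflectance), 0.5)
})
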