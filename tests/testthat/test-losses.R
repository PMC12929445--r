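test_that("NDVI mean squared error matches brute-force summation", {
  a <- array(0.2, c(2, 3, 3))
  expect_equal(mse_ndvi(a, a), 0)
  expect_equal(mse_ndvi(a + 0.2, a), 0.04, tolerance = 1e-12)
  set.seed(2)
  x <- array(rnorm(18), c(2, 3, 3))
  y <- array(rnorm(18), c(2, 3, 3))
  acc <- 0
  for (i in seq_len(2)) for (j in seq_len(3)) for (k in seq_len(3)) {
    acc <- acc + (x[i, j, k] - y[i, j, k])^2
  }
  expect_equal(mse_ndvi(x, y), acc / 18, tolerance = 1e-12)
  expect_error(mse_ndvi(x, array(0, c(3, 3, 2))), "shape")

  # invariant under a common permutation of both arrays
  perm <- sample(18)
  xp <- array(as.vector(x)[perm], c(2, 3, 3))
  yp <- array(as.vector(y)[perm], c(2, 3, 3))
  expect_equal(mse_ndvi(xp, yp), mse_ndvi(x, y), tolerance = 1e-12)
})

test_that("focal loss matches hand evaluation and the gamma = 0 reduction", {
  # single pixel, p_t = 0.5, alpha_t = 0.25, gamma = 2
  probs <- array(c(0.5, 0.5), c(2, 1, 1))
  lab <- matrix(0L, 1, 1)
  cfg <- loss_config(gamma = 2, alpha = c(0.25, 0.25))
  expect_equal(focal_loss(probs, lab, cfg), 0.25 * 0.25 * log(2),
               tolerance = 1e-12)

  # perfect prediction gives zero loss
  ph <- array(c(1, 0, 0, 1), c(2, 1, 2))
  labs <- matrix(c(0L, 1L), 1, 2)
  expect_equal(focal_loss(ph, labs, cfg), 0)

  # gamma = 0 is alpha-weighted cross-entropy (independent implementation)
  set.seed(5)
  K <- 4
  z <- matrix(rnorm(K * 30), K)
  p <- exp(z); p <- sweep(p, 2, colSums(p), "/")
  lab2 <- sample(0:(K - 1), 30, TRUE)
  al <- c(0.1, 0.5, 0.9, 0.3)
  ce <- mean(-al[lab2 + 1] * log(p[cbind(lab2 + 1, 1:30)]))
  got <- focal_loss(array(p, c(K, 5, 6)), matrix(lab2, 5, 6),
                    loss_config(gamma = 0, alpha = al))
  expect_equal(got, ce, tolerance = 1e-12)

  # modulation down-weights easy pixels: focal/CE at p_t = 0.9 is 0.01
  p9 <- array(c(0.9, 0.1), c(2, 1, 1))
  f2 <- focal_loss(p9, lab, loss_config(gamma = 2, alpha = c(0.5, 0.5)))
  f0 <- focal_loss(p9, lab, loss_config(gamma = 0, alpha = c(0.5, 0.5)))
  expect_equal(f2 / f0, 0.01, tolerance = 1e-12)

  expect_error(focal_loss(probs, matrix(5L, 1, 1), cfg), "labels")
  bad <- array(c(0.7, 0.7), c(2, 1, 1))
  expect_error(focal_loss(bad, lab, cfg), "sum to 1")
})

test_that("focal loss is non-negative and strictly decreasing in p_t", {
  cfg <- loss_config(gamma = 2, alpha = c(0.3, 0.3))
  pts <- seq(0.02, 0.98, by = 0.02)
  vals <- vapply(pts, function(pt) {
    focal_loss(array(c(pt, 1 - pt), c(2, 1, 1)), matrix(0L, 1, 1), cfg)
  }, 1)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) < 0))
  # same monotonicity at other gamma
  for (g in c(0.5, 1, 4)) {
    cfgg <- loss_config(gamma = g, alpha = c(0.3, 0.3))
    vg <- vapply(pts, function(pt) {
      focal_loss(array(c(pt, 1 - pt), c(2, 1, 1)), matrix(0L, 1, 1), cfgg)
    }, 1)
    expect_true(all(diff(vg) < 0))
  }
})

test_that("combined loss decomposes into focal + lambda * mse", {
  set.seed(9)
  K <- 3; H <- 4; T <- 2
  logits <- array(rnorm(K * H * H), c(K, H, H))
  labs <- matrix(sample(0:(K - 1), H * H, TRUE), H, H)
  np <- array(rnorm(T * H * H, sd = 0.2), c(T, H, H))
  nt <- array(rnorm(T * H * H, sd = 0.2), c(T, H, H))
  al <- c(0.2, 0.5, 0.8)

  cl <- combined_loss(logits, np, nt, labs,
                      loss_config(gamma = 2, alpha = al, ndvi_weight = 0.6))
  pm <- exp(logits); pm <- array(apply(pm, c(2, 3), function(v) v / sum(v)),
                                 dim(pm))
  f_ind <- focal_loss(pm, labs, loss_config(gamma = 2, alpha = al))
  expect_equal(cl$focal, f_ind, tolerance = 1e-10)
  expect_equal(cl$mse, mse_ndvi(np, nt), tolerance = 1e-12)
  expect_equal(cl$total, cl$focal + 0.6 * cl$mse, tolerance = 1e-12)

  # lambda = 0 leaves only the focal term
  c0 <- combined_loss(logits, np, nt, labs,
                      loss_config(gamma = 2, alpha = al, ndvi_weight = 0))
  expect_equal(c0$total, c0$focal)

  # perfect predictions on both heads
  big <- array(-50, c(K, H, H))
  for (i in 1:H) for (j in 1:H) big[labs[i, j] + 1, i, j] <- 50
  cp <- combined_loss(big, nt, nt, labs,
                      loss_config(gamma = 2, alpha = al, ndvi_weight = 1))
  expect_equal(cp$total, 0, tolerance = 1e-10)
})

test_that("masking a class removes it from the focal objective", {
  probs <- array(rep(c(0.6, 0.3, 0.1), 4), c(3, 2, 2))
  labs <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  cfg_all <- loss_config(gamma = 2, alpha = c(0.3, 0.3, 0.3))
  cfg_m <- loss_config(gamma = 2, alpha = c(0.3, 0.3, 0.3), mask_class = 0L)
  l_all <- focal_loss(probs, labs, cfg_all)
  l_m <- focal_loss(probs, labs, cfg_m)
  # masked loss averages only over the two non-background pixels
  pt <- c(0.3, 0.1)
  expect_equal(l_m, mean(-0.3 * (1 - pt)^2 * log(pt)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l_all, l_m)))
})

test_that("the focal term weight rescales the combined objective only", {
  set.seed(12)
  K <- 3; H <- 3; T <- 2
  logits <- array(rnorm(K * H * H), c(K, H, H))
  labs <- matrix(sample(0:(K - 1), H * H, TRUE), H, H)
  np <- array(rnorm(T * H * H, sd = 0.2), c(T, H, H))
  nt <- array(rnorm(T * H * H, sd = 0.2), c(T, H, H))
  al <- c(0.2, 0.5, 0.8)
  base <- combined_loss(logits, np, nt, labs,
                        loss_config(alpha = al, ndvi_weight = 0.5))
  scaled <- combined_loss(logits, np, nt, labs,
                          loss_config(alpha = al, ndvi_weight = 0.5,
                                      focal_weight = 3))
  expect_equal(scaled$focal, base$focal)          # reported term unscaled
  expect_equal(scaled$mse, base$mse)
  expect_equal(scaled$total, 3 * base$focal + 0.5 * base$mse,
               tolerance = 1e-12)
})
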