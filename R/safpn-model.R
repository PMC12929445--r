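# The (3+2)D split-attention feature pyramid network.
#
# Data flow: a 3D convolutional stem runs jointly over (time, height, width)
# of the T x B x H x W reflectance stack; the resulting temporal feature
# volume feeds (a) a linear 1x1x1 NDVI regression head (one value per date
# per pixel) and (b), after temporal collapse, a four-stage 2D encoder
# (c2..c5) whose maps are fused top-down through lateral connections into a
# pyramid (p2..p5) with a split-attention module at every level. The
# classification head upsamples p2 to the input resolution and produces
# per-pixel class logits with a 3x3 convolution.

#' Network configuration
#'
#' @param stage_channels Output widths of encoder stages c2..c5.
#' @param stage_depth_preset One of `"plain"` (two 3x3 convolutions per
#'   stage), `"resnet50"`, `"resnet101"` (bottleneck stacks of depth
#'   3-4-6-3 / 3-4-23-3).
#' @param pyramid_channels Width of the fused pyramid levels p2..p5.
#' @param n_classes Number of label classes (class 0 = "others").
#' @param n_dates Number of acquisitions T in the input series.
#' @param n_bands Number of spectral bands B.
#' @param patch_size Spatial side of the input patches, pixels.
#' @param temporal_collapse How the 3D feature volume becomes 2D: `"mean"`
#'   or `"max"` over the time axis.
#' @param stem_channels Width of the 3D stem.
#' @param use_sa Apply split-attention modules in the pyramid; with `FALSE`
#'   the model is the plain (3+2)D FPN baseline.
#' @param sa An [sa_config()].
#' @return An object of class `safpn_config`.
#' @details The stride schedule follows the reference backbones: stage c2
#'   keeps the stem resolution and c3..c5 downsample with stride 2, except
#'   that a stage's stride is skipped whenever it would push the spatial
#'   side below 3 pixels, so the top pyramid level stays well-defined for
#'   24 px and 48 px patches alike.
#' @export
safpn_config <- function(stage_channels = c(256L, 512L, 1024L, 2048L),
                         stage_depth_preset = c("plain", "resnet50", "resnet101"),
                         pyramid_channels = 256L,
                         n_classes = 8L,
                         n_dates = 20L,
                         n_bands = 13L,
                         patch_size = 24L,
                         temporal_collapse = c("mean", "max"),
                         stem_channels = 64L,
                         use_sa = TRUE,
                         sa = sa_config()) {
  stage_depth_preset <- match.arg(stage_depth_preset)
  temporal_collapse <- match.arg(temporal_collapse)
  stopifnot(length(stage_channels) == 4, all(stage_channels > 0),
            pyramid_channels > 0, n_classes >= 2, n_dates >= 1,
            n_bands >= 1, stem_channels >= 1)
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L) {
    stop("patch_size must be at least 3 pixels")
  }
  if (pyramid_channels %% sa$cardinality != 0L) {
    stop("pyramid_channels must be divisible by the SA cardinality")
  }
  # ResNet-style schedule: the first stage keeps the stem resolution
  # (conv2_x does not downsample in the reference backbones), stages 3..5
  # stride by 2, and a stage's stride is skipped when it would push the
  # spatial side below 3
  sides <- integer(4); strides <- integer(4)
  cur <- patch_size
  for (i in 1:4) {
    if (i == 1L) {
      strides[i] <- 1L
      sides[i] <- cur
      next
    }
    nxt <- conv2d_out_side(cur, 3L, 2L)
    if (nxt < 3L) {
      strides[i] <- 1L
    } else {
      strides[i] <- 2L
      cur <- nxt
    }
    sides[i] <- cur
  }
  structure(list(stage_channels = as.integer(stage_channels),
                 stage_depth_preset = stage_depth_preset,
                 pyramid_channels = as.integer(pyramid_channels),
                 n_classes = as.integer(n_classes),
                 n_dates = as.integer(n_dates),
                 n_bands = as.integer(n_bands),
                 patch_size = patch_size,
                 temporal_collapse = temporal_collapse,
                 stem_channels = as.integer(stem_channels),
                 use_sa = isTRUE(use_sa),
                 sa = sa,
                 stage_sides = sides,
                 stage_strides = strides),
            class = "safpn_config")
}

stage_depths <- function(preset) {
  switch(preset,
         plain = c(1L, 1L, 1L, 1L),
         resnet50 = c(3L, 4L, 6L, 3L),
         resnet101 = c(3L, 4L, 23L, 3L))
}

new_plain_unit <- function(cin, cout, stride) {
  list(kind = "plain",
       conv1 = new_conv2d(cin, cout, 3L, stride, bias = FALSE),
       bn1 = new_bn(cout),
       conv2 = new_conv2d(cout, cout, 3L, 1L, bias = FALSE),
       bn2 = new_bn(cout))
}

new_bottleneck_unit <- function(cin, cout, stride) {
  cmid <- max(1L, cout %/% 4L)
  u <- list(kind = "bottleneck",
            conva = new_conv2d(cin, cmid, 1L, stride, bias = FALSE),
            bna = new_bn(cmid),
            convb = new_conv2d(cmid, cmid, 3L, 1L, bias = FALSE),
            bnb = new_bn(cmid),
            convc = new_conv2d(cmid, cout, 1L, 1L, bias = FALSE),
            bnc = new_bn(cout))
  if (cin != cout || stride != 1L) {
    u$proj <- new_conv2d(cin, cout, 1L, stride, bias = FALSE)
    u$bnp <- new_bn(cout)
  }
  u
}

#' Build a (3+2)D SAFPN model
#'
#' @param config A [safpn_config()].
#' @param seed Integer seed for parameter initialization (He fan-in for
#'   convolutions; the final attention dense layers start at zero so the
#'   network begins in the uniform-attention limit).
#' @return An object of class `safpn_model` (an environment holding the
#'   learnable parameters).
#' @export
safpn_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "safpn_config"))
  set.seed(as.integer(seed))
  cf <- config
  m <- new.env(parent = emptyenv())
  m$config <- cf
  P <- cf$pyramid_channels
  m$stem_conv <- new_conv3d(cf$n_bands, cf$stem_channels, 3L, bias = FALSE)
  m$stem_bn <- new_bn(cf$stem_channels)
  m$ndvi_conv <- new_conv3d(cf$stem_channels, 1L, 1L, bias = TRUE)
  depths <- stage_depths(cf$stage_depth_preset)
  cin <- cf$stem_channels
  m$stages <- vector("list", 4)
  for (i in 1:4) {
    cout <- cf$stage_channels[i]
    units <- vector("list", depths[i])
    for (u in seq_len(depths[i])) {
      s <- if (u == 1L) cf$stage_strides[i] else 1L
      units[[u]] <- if (cf$stage_depth_preset == "plain") {
        new_plain_unit(if (u == 1L) cin else cout, cout, s)
      } else {
        new_bottleneck_unit(if (u == 1L) cin else cout, cout, s)
      }
    }
    m$stages[[i]] <- units
    cin <- cout
  }
  m$lat <- lapply(1:4, function(i) new_conv2d(cf$stage_channels[i], P, 1L,
                                              bias = TRUE))
  m$sa <- if (cf$use_sa) lapply(1:4, function(i) new_sa_module(P, cf$sa)) else NULL
  m$head_conv <- new_conv2d(P, cf$n_classes, 3L, 1L, bias = TRUE)
  class(m) <- "safpn_model"
  m
}

# flat named list of parameter-holding layer environments
model_layers <- function(m) {
  out <- list(stem.conv = m$stem_conv, stem.bn = m$stem_bn,
              ndvi.conv = m$ndvi_conv)
  for (i in 1:4) {
    for (u in seq_along(m$stages[[i]])) {
      unit <- m$stages[[i]][[u]]
      pre <- sprintf("stage%d.u%d.", i + 1L, u)
      for (nm in setdiff(names(unit), "kind")) {
        out[[paste0(pre, nm)]] <- unit[[nm]]
      }
    }
    out[[sprintf("lat%d", i + 1L)]] <- m$lat[[i]]
    if (!is.null(m$sa)) {
      mod <- m$sa[[i]]
      out[[sprintf("sa%d.bconv", i + 1L)]] <- mod$bconv
      for (k in seq_along(mod$core$groups)) {
        g <- mod$core$groups[[k]]
        out[[sprintf("sa%d.g%d.d1", i + 1L, k)]] <- g$d1
        out[[sprintf("sa%d.g%d.bn1", i + 1L, k)]] <- g$bn1
        out[[sprintf("sa%d.g%d.d2", i + 1L, k)]] <- g$d2
      }
    }
  }
  out$head.conv <- m$head_conv
  out
}

#' Number of learnable parameters
#'
#' @param model A [safpn_model()].
#' @return Integer count of scalar learnable parameters.
#' @export
safpn_num_params <- function(model) {
  sum(vapply(model_layers(model),
             function(l) sum(vapply(l$par, length, 1L)), 1L))
}

zero_grads <- function(m) {
  for (l in model_layers(m)) {
    for (nm in names(l$par)) l$grad[[nm]][] <- 0
  }
  invisible(m)
}

## ---- forward ----------------------------------------------------------------

unit_f <- function(unit, x, H, W, N, train) {
  if (unit$kind == "plain") {
    c1 <- conv2d_f(unit$conv1, x, H, W, N)
    r1 <- relu_f(c1$y)
    b1 <- bn_f(unit$bn1, r1$y, train)
    c2 <- conv2d_f(unit$conv2, b1$y, c1$Ho, c1$Wo, N)
    r2 <- relu_f(c2$y)
    b2 <- bn_f(unit$bn2, r2$y, train)
    list(y = b2$y, Ho = c1$Ho, Wo = c1$Wo,
         cache = list(x = x, m1 = r1$mask, b1 = b1, x2 = b1$y,
                      m2 = r2$mask, b2 = b2))
  } else {
    ca <- conv2d_f(unit$conva, x, H, W, N)
    ra <- relu_f(ca$y); ba <- bn_f(unit$bna, ra$y, train)
    cb <- conv2d_f(unit$convb, ba$y, ca$Ho, ca$Wo, N)
    rb <- relu_f(cb$y); bb <- bn_f(unit$bnb, rb$y, train)
    cc2 <- conv2d_f(unit$convc, bb$y, ca$Ho, ca$Wo, N)
    rc <- relu_f(cc2$y); bc <- bn_f(unit$bnc, rc$y, train)
    if (!is.null(unit$proj)) {
      pj <- conv2d_f(unit$proj, x, H, W, N)
      rp <- relu_f(pj$y); bp <- bn_f(unit$bnp, rp$y, train)
      skip <- bp$y
      pcache <- list(mp = rp$mask, bp = bp)
    } else {
      skip <- x
      pcache <- NULL
    }
    list(y = bc$y + skip, Ho = ca$Ho, Wo = ca$Wo,
         cache = list(x = x, ma = ra$mask, ba = ba, xb = ba$y,
                      mb = rb$mask, bb = bb, xc = bb$y, mc = rc$mask,
                      bc = bc, proj = pcache))
  }
}

unit_b <- function(unit, cache, dy, H, W, N, Ho, Wo) {
  if (unit$kind == "plain") {
    d <- bn_b(unit$bn2, cache$b2, dy)
    d <- relu_b(cache$m2, d)
    d <- conv2d_b(unit$conv2, cache$x2, d, Ho, Wo, N)
    d <- bn_b(unit$bn1, cache$b1, d)
    d <- relu_b(cache$m1, d)
    conv2d_b(unit$conv1, cache$x, d, H, W, N)
  } else {
    dmain <- bn_b(unit$bnc, cache$bc, dy)
    dmain <- relu_b(cache$mc, dmain)
    dmain <- conv2d_b(unit$convc, cache$xc, dmain, Ho, Wo, N)
    dmain <- bn_b(unit$bnb, cache$bb, dmain)
    dmain <- relu_b(cache$mb, dmain)
    dmain <- conv2d_b(unit$convb, cache$xb, dmain, Ho, Wo, N)
    dmain <- bn_b(unit$bna, cache$ba, dmain)
    dmain <- relu_b(cache$ma, dmain)
    dx <- conv2d_b(unit$conva, cache$x, dmain, H, W, N)
    if (!is.null(unit$proj)) {
      dskip <- bn_b(unit$bnp, cache$proj$bp, dy)
      dskip <- relu_b(cache$proj$mp, dskip)
      dx <- dx + conv2d_b(unit$proj, cache$x, dskip, H, W, N)
    } else {
      dx <- dx + dy
    }
    dx
  }
}

# internal batched forward; x is (B, H*W*T, N)
model_forward <- function(m, x, N, train = FALSE, keep_cache = train) {
  cf <- m$config
  H <- cf$patch_size; W <- cf$patch_size; T <- cf$n_dates
  HW <- H * W
  cc <- list(x = x)
  s1 <- conv3d_f(m$stem_conv, x, H, W, T, N)
  r1 <- relu_f(s1)
  b1 <- bn_f(m$stem_bn, r1$y, train)
  V <- b1$y
  cc$stem_mask <- r1$mask; cc$stem_bn <- b1
  nd <- conv3d_f(m$ndvi_conv, V, H, W, T, N)
  ndvi <- matrix(nd, HW * T, N)
  cl <- collapse_f(V, HW, T, N, cf$temporal_collapse)
  cc$collapse <- cl
  cc$V <- V
  cur <- cl$y
  side <- H
  feats <- vector("list", 4)
  sides <- integer(4)
  cc$stages <- vector("list", 4)
  for (i in 1:4) {
    cc$stages[[i]] <- vector("list", length(m$stages[[i]]))
    for (u in seq_along(m$stages[[i]])) {
      res <- unit_f(m$stages[[i]][[u]], cur, side, side, N, train)
      cc$stages[[i]][[u]] <- list(cache = res$cache, Hin = side, Hout = res$Ho)
      cur <- res$y
      side <- res$Ho
    }
    feats[[i]] <- cur
    sides[i] <- side
  }
  cc$feats <- feats
  cc$sides <- sides
  lat <- vector("list", 4)
  for (i in 1:4) {
    lat[[i]] <- conv2d_f(m$lat[[i]], feats[[i]], sides[i], sides[i], N)$y
  }
  cc$lat_in <- feats
  p <- vector("list", 4)
  merged <- vector("list", 4)
  sa_cc <- vector("list", 4)
  merged[[4]] <- lat[[4]]
  if (cf$use_sa) {
    sres <- sa_module_f(m$sa[[4]], merged[[4]], sides[4], sides[4], N, train)
    p[[4]] <- sres$y; sa_cc[[4]] <- sres
  } else p[[4]] <- merged[[4]]
  for (i in 3:1) {
    f <- sides[i] %/% sides[i + 1]
    if (f * sides[i + 1] != sides[i]) {
      stop("spatial mismatch between lateral and upsampled pyramid maps")
    }
    up <- upsample_f(p[[i + 1]], sides[i + 1], sides[i + 1], N, f)
    merged[[i]] <- lat[[i]] + up
    if (cf$use_sa) {
      sres <- sa_module_f(m$sa[[i]], merged[[i]], sides[i], sides[i], N, train)
      p[[i]] <- sres$y; sa_cc[[i]] <- sres
    } else p[[i]] <- merged[[i]]
  }
  cc$merged <- merged
  cc$sa <- sa_cc
  cc$p <- p
  f_head <- H %/% sides[1]
  u <- upsample_f(p[[1]], sides[1], sides[1], N, f_head)
  cc$head_in <- u
  logits <- conv2d_f(m$head_conv, u, H, W, N)$y
  out <- list(logits = logits, ndvi = ndvi)
  if (keep_cache) out$cache <- cc
  out
}

# internal backward; dlogits (K, HW, N), dndvi (HW*T, N)
# upto = "input" runs the full chain; "volume" stops at the shared temporal
# feature volume and returns its gradient (used for temporal attribution)
model_backward <- function(m, cc, dlogits, dndvi, N, upto = c("input", "volume"),
                           need_input_grad = FALSE) {
  upto <- match.arg(upto)
  cf <- m$config
  H <- cf$patch_size; W <- cf$patch_size; T <- cf$n_dates
  HW <- H * W
  sides <- cc$sides
  du <- conv2d_b(m$head_conv, cc$head_in, dlogits, H, W, N)
  f_head <- H %/% sides[1]
  dp <- vector("list", 4)
  dp[[1]] <- upsample_b(du, sides[1], sides[1], N, f_head)
  dfeat <- vector("list", 4)
  for (i in 1:3) {
    dm <- if (cf$use_sa) {
      sa_module_b(m$sa[[i]], cc$merged[[i]], cc$sa[[i]], dp[[i]],
                  sides[i], sides[i], N)
    } else dp[[i]]
    dfeat[[i]] <- conv2d_b(m$lat[[i]], cc$lat_in[[i]], dm,
                           sides[i], sides[i], N)
    f <- sides[i] %/% sides[i + 1]
    dnext <- upsample_b(dm, sides[i + 1], sides[i + 1], N, f)
    dp[[i + 1]] <- if (is.null(dp[[i + 1]])) dnext else dp[[i + 1]] + dnext
  }
  dm <- if (cf$use_sa) {
    sa_module_b(m$sa[[4]], cc$merged[[4]], cc$sa[[4]], dp[[4]],
                sides[4], sides[4], N)
  } else dp[[4]]
  dfeat[[4]] <- conv2d_b(m$lat[[4]], cc$lat_in[[4]], dm, sides[4], sides[4], N)
  dcur <- dfeat[[4]]
  for (i in 4:1) {
    if (i < 4) dcur <- dcur + dfeat[[i]]
    for (u in rev(seq_along(m$stages[[i]]))) {
      st <- cc$stages[[i]][[u]]
      dcur <- unit_b(m$stages[[i]][[u]], st$cache, dcur,
                     st$Hin, st$Hin, N, st$Hout, st$Hout)
    }
  }
  dV <- collapse_b(cc$collapse, dcur, HW, T, N, cf$temporal_collapse)
  dV <- dV + conv3d_b(m$ndvi_conv, cc$V, array(dndvi, c(1L, HW * T, N)),
                      H, W, T, N)
  if (upto == "volume") return(list(dvolume = dV))
  d <- bn_b(m$stem_bn, cc$stem_bn, dV)
  d <- relu_b(cc$stem_mask, d)
  dx <- conv3d_b(m$stem_conv, cc$x, d, H, W, T, N, need_dx = need_input_grad)
  list(dinput = dx)
}

## ---- public forward on patches ----------------------------------------------

# reflectance (T, B, H, W) -> internal volume (B, H*W*T, 1)
vol_from_reflectance <- function(refl) {
  d <- dim(refl)
  array(aperm(refl, c(2, 3, 4, 1)), c(d[2], d[3] * d[4] * d[1], 1L))
}

#' Run the network on one patch
#'
#' @param model A [safpn_model()].
#' @param reflectance Numeric array `(T, B, H, W)` matching the model
#'   configuration, or a `ts_patch` object.
#' @param train Logical; batch-statistics mode for batch norm.
#' @param features If `TRUE`, also return the encoder hierarchy c2..c5 and
#'   the fused pyramid p2..p5 as arrays `(C, h, w)`.
#' @return A list with `logits` (`n_classes x H x W`), `ndvi`
#'   (`T x H x W`, linear output of the regression head), and optionally
#'   `features`.
#' @export
safpn_forward <- function(model, reflectance, train = FALSE, features = FALSE) {
  if (inherits(reflectance, "ts_patch")) reflectance <- reflectance$reflectance
  cf <- model$config
  d <- dim(reflectance)
  if (length(d) != 4) stop("reflectance must be a (T, B, H, W) array")
  if (d[1] != cf$n_dates) {
    stop(sprintf("model expects T = %d acquisitions, input has %d",
                 cf$n_dates, d[1]))
  }
  if (d[2] != cf$n_bands || d[3] != cf$patch_size || d[4] != cf$patch_size) {
    stop(sprintf("model expects (B, H, W) = (%d, %d, %d), input is (%d, %d, %d)",
                 cf$n_bands, cf$patch_size, cf$patch_size, d[2], d[3], d[4]))
  }
  x <- vol_from_reflectance(reflectance)
  out <- model_forward(model, x, N = 1L, train = train, keep_cache = features)
  H <- cf$patch_size
  res <- list(
    logits = array(out$logits[, , 1], c(cf$n_classes, H, H)),
    ndvi = aperm(array(out$ndvi[, 1], c(H, H, cf$n_dates)), c(3, 1, 2)))
  if (features) {
    cc <- out$cache
    fe <- list()
    for (i in 1:4) {
      fe[[paste0("c", i + 1L)]] <- array(cc$feats[[i]][, , 1],
                                         c(dim(cc$feats[[i]])[1], cc$sides[i], cc$sides[i]))
      fe[[paste0("p", i + 1L)]] <- array(cc$p[[i]][, , 1],
                                         c(dim(cc$p[[i]])[1], cc$sides[i], cc$sides[i]))
    }
    res$features <- fe
  }
  res
}

## ---- checkpoints ------------------------------------------------------------

params_get <- function(m) {
  lapply(model_layers(m), function(l) {
    out <- list(par = l$par)
    if (l$kind == "bn") { out$rm <- l$rm; out$rv <- l$rv }
    out
  })
}

params_set <- function(m, snap) {
  ls <- model_layers(m)
  stopifnot(identical(sort(names(ls)), sort(names(snap))))
  for (nm in names(ls)) {
    l <- ls[[nm]]
    for (pn in names(l$par)) l$par[[pn]] <- snap[[nm]]$par[[pn]]
    if (l$kind == "bn") { l$rm <- snap[[nm]]$rm; l$rv <- snap[[nm]]$rv }
  }
  invisible(m)
}

#' Save model parameters and configuration
#'
#' @param model A [safpn_model()].
#' @param path Destination file.
#' @param extra Optional named list stored alongside (e.g. class names,
#'   training history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(config = model$config, params = params_get(model), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A list with `model` (rebuilt [safpn_model()]) and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- safpn_model(obj$config, seed = 1L)
  params_set(model, obj$params)
  list(model = model, extra = obj$extra)
}
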