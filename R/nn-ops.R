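# Low-level tensor primitives for the network.
#
# Feature maps are arrays of dim (C, M, N): C channels, M flattened positions
# (pixel index runs rows fastest, then columns, then -- for volumes -- time),
# N samples in the batch. Convolutions are evaluated as one GEMM per kernel
# offset against a zero-padded gather of the input, which keeps all the
# arithmetic inside BLAS; the gather map per offset is injective, so the
# backward scatter needs no duplicate handling.

.safpn_map_cache <- new.env(parent = emptyenv())

conv2d_out_side <- function(side, k, s) {
  pad <- (k - 1L) %/% 2L
  as.integer((side + 2L * pad - k) %/% s + 1L)
}

# gather maps for a k x k kernel over an H x W grid, stride s, "same" padding
conv2d_maps <- function(H, W, k, s) {
  key <- paste("c2", H, W, k, s, sep = "_")
  hit <- .safpn_map_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Ho <- conv2d_out_side(H, k, s)
  Wo <- conv2d_out_side(W, k, s)
  idx <- vector("list", k * k)
  m <- 1L
  for (b in seq_len(k)) {
    for (a in seq_len(k)) {
      hi <- (seq_len(Ho) - 1L) * s + a - pad
      wi <- (seq_len(Wo) - 1L) * s + b - pad
      lin <- outer(hi, (wi - 1L) * H, "+")
      lin[hi < 1L | hi > H, ] <- NA_integer_
      lin[, wi < 1L | wi > W] <- NA_integer_
      idx[[m]] <- as.integer(lin)
      m <- m + 1L
    }
  }
  out <- list(Ho = Ho, Wo = Wo, idx = idx)
  assign(key, out, envir = .safpn_map_cache)
  out
}

# gather maps for a k^3 kernel over an (H, W, T) volume, stride 1
conv3d_maps <- function(H, W, T, k) {
  key <- paste("c3", H, W, T, k, sep = "_")
  hit <- .safpn_map_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  HW <- H * W
  hs <- seq_len(H); ws <- seq_len(W); ts <- seq_len(T)
  idx <- vector("list", k^3)
  m <- 1L
  for (ct in seq_len(k)) {
    for (b in seq_len(k)) {
      for (a in seq_len(k)) {
        hi <- hs + a - 1L - pad
        wi <- ws + b - 1L - pad
        ti <- ts + ct - 1L - pad
        lin2 <- outer(hi, (wi - 1L) * H, "+")
        lin2[hi < 1L | hi > H, ] <- NA_integer_
        lin2[, wi < 1L | wi > W] <- NA_integer_
        lin <- outer(as.integer(lin2), (ti - 1L) * HW, "+")
        lin[, ti < 1L | ti > T] <- NA_integer_
        idx[[m]] <- as.integer(lin)
        m <- m + 1L
      }
    }
  }
  out <- list(idx = idx)
  assign(key, out, envir = .safpn_map_cache)
  out
}

# replicate a single-sample gather map across a batch; NA (padding) -> 0
batch_gather_idx <- function(idx, M, N) {
  big <- as.integer(outer(idx, (seq_len(N) - 1L) * M, "+"))
  big[is.na(big)] <- 0L
  big
}

.batched_maps <- function(maps, M, N, key) {
  bkey <- paste(key, M, N, sep = "_")
  hit <- .safpn_map_cache[[bkey]]
  if (!is.null(hit)) return(hit)
  out <- lapply(maps$idx, batch_gather_idx, M = M, N = N)
  assign(bkey, out, envir = .safpn_map_cache)
  out
}

## ---- layers as parameter environments -------------------------------------

new_layer <- function(kind, par, extra = list()) {
  l <- new.env(parent = emptyenv())
  l$kind <- kind
  l$par <- par
  l$grad <- lapply(par, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  class(l) <- c(paste0("safpn_", kind), "safpn_layer")
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_conv2d <- function(cin, cout, k = 3L, stride = 1L, bias = TRUE,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "he") he_init(c(cout, cin, k, k), cin * k * k) else
    array(0, c(cout, cin, k, k))
  par <- list(W = W)
  if (bias) par$b <- numeric(cout)
  new_layer("conv2d", par, list(k = as.integer(k), s = as.integer(stride),
                                cin = cin, cout = cout))
}

new_conv3d <- function(cin, cout, k = 3L, bias = TRUE) {
  W <- he_init(c(cout, cin, k, k, k), cin * k^3)
  par <- list(W = W)
  if (bias) par$b <- numeric(cout)
  new_layer("conv3d", par, list(k = as.integer(k), cin = cin, cout = cout))
}

new_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("bn", list(gamma = rep(1, C), beta = rep(0, C)),
                 list(eps = eps, momentum = momentum, C = C))
  l$rm <- rep(0, C)
  l$rv <- rep(1, C)
  l
}

new_dense <- function(nin, nout, init = c("he", "zero"), bias = TRUE) {
  init <- match.arg(init)
  W <- if (init == "he") he_init(c(nout, nin), nin) else array(0, c(nout, nin))
  par <- list(W = W)
  if (bias) par$b <- numeric(nout)   # omitted when a batch norm follows
  new_layer("dense", par, list(nin = nin, nout = nout))
}

## ---- conv2d ----------------------------------------------------------------

conv2d_f <- function(l, x, H, W, N) {
  C <- dim(x)[1]
  if (l$k == 1L) {
    s <- l$s
    xm <- matrix(x, C, H * W * N)
    if (s > 1L) {
      keep <- as.integer(outer(
        as.integer(outer(seq(1L, H, by = s), (seq(1L, W, by = s) - 1L) * H, "+")),
        (seq_len(N) - 1L) * H * W, "+"))
      xm <- xm[, keep, drop = FALSE]
      Ho <- length(seq(1L, H, by = s)); Wo <- length(seq(1L, W, by = s))
    } else { Ho <- H; Wo <- W }
    Wm <- matrix(l$par$W, l$cout, C)
    y <- Wm %*% xm
    if (!is.null(l$par$b)) y <- y + l$par$b
    return(list(y = array(y, c(l$cout, Ho * Wo, N)), Ho = Ho, Wo = Wo))
  }
  mp <- conv2d_maps(H, W, l$k, l$s)
  bidx <- .batched_maps(mp, H * W, N, paste("c2", H, W, l$k, l$s, sep = "_"))
  xm <- matrix(x, C, H * W * N)
  y <- matrix(0, l$cout, mp$Ho * mp$Wo * N)
  m <- 1L
  for (b in seq_len(l$k)) {
    for (a in seq_len(l$k)) {
      Wm <- matrix(l$par$W[, , a, b], l$cout, C)
      y <- y + Wm %*% cpp_gather(xm, bidx[[m]])
      m <- m + 1L
    }
  }
  if (!is.null(l$par$b)) y <- y + l$par$b
  list(y = array(y, c(l$cout, mp$Ho * mp$Wo, N)), Ho = mp$Ho, Wo = mp$Wo)
}

conv2d_b <- function(l, x, dy, H, W, N, need_dx = TRUE) {
  C <- dim(x)[1]
  dym <- matrix(dy, l$cout, length(dy) / l$cout)
  if (!is.null(l$par$b)) l$grad$b <- l$grad$b + rowSums(dym)
  if (l$k == 1L) {
    s <- l$s
    xm <- matrix(x, C, H * W * N)
    if (s > 1L) {
      keep <- as.integer(outer(
        as.integer(outer(seq(1L, H, by = s), (seq(1L, W, by = s) - 1L) * H, "+")),
        (seq_len(N) - 1L) * H * W, "+"))
      xs <- xm[, keep, drop = FALSE]
      l$grad$W <- l$grad$W + array(tcrossprod(dym, xs), dim(l$par$W))
      dx <- matrix(0, C, H * W * N)
      dx[, keep] <- crossprod(matrix(l$par$W, l$cout, C), dym)
    } else {
      l$grad$W <- l$grad$W + array(tcrossprod(dym, xm), dim(l$par$W))
      dx <- crossprod(matrix(l$par$W, l$cout, C), dym)
    }
    return(array(dx, c(C, H * W, N)))
  }
  mp <- conv2d_maps(H, W, l$k, l$s)
  bidx <- .batched_maps(mp, H * W, N, paste("c2", H, W, l$k, l$s, sep = "_"))
  xm <- matrix(x, C, H * W * N)
  if (need_dx) dxm <- matrix(0, C, H * W * N)
  m <- 1L
  for (b in seq_len(l$k)) {
    for (a in seq_len(l$k)) {
      id <- bidx[[m]]
      l$grad$W[, , a, b] <- l$grad$W[, , a, b] +
        tcrossprod(dym, cpp_gather(xm, id))
      if (need_dx) {
        dcols <- crossprod(matrix(l$par$W[, , a, b], l$cout, C), dym)
        cpp_scatter_add(dxm, id, dcols)
      }
      m <- m + 1L
    }
  }
  if (!need_dx) return(NULL)
  array(dxm, c(C, H * W, N))
}

## ---- conv3d (stride 1, "same") --------------------------------------------

conv3d_f <- function(l, x, H, W, T, N) {
  C <- dim(x)[1]
  M <- H * W * T
  if (l$k == 1L) {
    xm <- matrix(x, C, M * N)
    y <- matrix(l$par$W, l$cout, C) %*% xm
    if (!is.null(l$par$b)) y <- y + l$par$b
    return(array(y, c(l$cout, M, N)))
  }
  mp <- conv3d_maps(H, W, T, l$k)
  bidx <- .batched_maps(mp, M, N, paste("c3", H, W, T, l$k, sep = "_"))
  xm <- matrix(x, C, M * N)
  y <- matrix(0, l$cout, M * N)
  m <- 1L
  for (ct in seq_len(l$k)) for (b in seq_len(l$k)) for (a in seq_len(l$k)) {
    y <- y + matrix(l$par$W[, , a, b, ct], l$cout, C) %*%
      cpp_gather(xm, bidx[[m]])
    m <- m + 1L
  }
  if (!is.null(l$par$b)) y <- y + l$par$b
  array(y, c(l$cout, M, N))
}

conv3d_b <- function(l, x, dy, H, W, T, N, need_dx = TRUE) {
  C <- dim(x)[1]
  M <- H * W * T
  dym <- matrix(dy, l$cout, M * N)
  if (!is.null(l$par$b)) l$grad$b <- l$grad$b + rowSums(dym)
  if (l$k == 1L) {
    xm <- matrix(x, C, M * N)
    l$grad$W <- l$grad$W + array(tcrossprod(dym, xm), dim(l$par$W))
    if (!need_dx) return(NULL)
    dx <- crossprod(matrix(l$par$W, l$cout, C), dym)
    return(array(dx, c(C, M, N)))
  }
  k3 <- l$k^3
  mp <- conv3d_maps(H, W, T, l$k)
  bidx <- .batched_maps(mp, M, N, paste("c3", H, W, T, l$k, sep = "_"))
  xm <- matrix(x, C, M * N)
  if (need_dx) dxm <- matrix(0, C, M * N)
  m <- 1L
  for (ct in seq_len(l$k)) for (b in seq_len(l$k)) for (a in seq_len(l$k)) {
    id <- bidx[[m]]
    l$grad$W[, , a, b, ct] <- l$grad$W[, , a, b, ct] +
      tcrossprod(dym, cpp_gather(xm, id))
    if (need_dx) {
      dcols <- crossprod(matrix(l$par$W[, , a, b, ct], l$cout, C), dym)
      cpp_scatter_add(dxm, id, dcols)
    }
    m <- m + 1L
  }
  if (!need_dx) return(NULL)
  array(dxm, c(C, M, N))
}

## ---- batch norm (per-channel over batch x positions) -----------------------

bn_f <- function(l, x, train) {
  d <- dim(x)
  xm <- matrix(x, d[1], prod(d[-1]))
  if (train) {
    mu <- rowMeans(xm)
    v <- pmax(rowMeans(xm * xm) - mu * mu, 0)
    istd <- 1 / sqrt(v + l$eps)
    l$rm <- (1 - l$momentum) * l$rm + l$momentum * mu
    l$rv <- (1 - l$momentum) * l$rv + l$momentum * v
  } else {
    mu <- l$rm
    istd <- 1 / sqrt(l$rv + l$eps)
  }
  res <- cpp_bn_scale(xm, mu, istd, l$par$gamma, l$par$beta)
  y <- res$y
  dim(y) <- d
  list(y = y, xhat = res$xhat, istd = istd)
}

bn_b <- function(l, cache, dy) {
  d <- dim(dy)
  dym <- matrix(dy, d[1], prod(d[-1]))
  res <- cpp_bn_bwd(dym, cache$xhat, l$par$gamma, cache$istd)
  l$grad$gamma <- l$grad$gamma + res$dgamma
  l$grad$beta <- l$grad$beta + res$dbeta
  dx <- res$dx
  dim(dx) <- d
  dx
}

# NOTE: relu_f mutates its (freshly allocated) input in place
relu_f <- function(x) {
  mask <- cpp_relu_inplace(x)
  list(y = x, mask = mask)
}

relu_b <- function(mask, dy) {
  cpp_mask_zero(dy, mask)
  dy
}

## ---- nearest-neighbour upsampling ------------------------------------------

upsample_f <- function(x, H, W, N, f) {
  if (f == 1L) return(x)
  C <- dim(x)[1]
  Hf <- H * f; Wf <- W * f
  hin <- (seq_len(Hf) - 1L) %/% f + 1L
  win <- (seq_len(Wf) - 1L) %/% f + 1L
  lin <- as.integer(outer(hin, (win - 1L) * H, "+"))
  bidx <- batch_gather_idx(lin, H * W, N)
  array(cpp_gather(matrix(x, C, H * W * N), bidx), c(C, Hf * Wf, N))
}

upsample_b <- function(dy, H, W, N, f) {
  if (f == 1L) return(dy)
  C <- dim(dy)[1]
  Hf <- H * f; Wf <- W * f
  dym <- matrix(dy, C, Hf * Wf * N)
  dx <- matrix(0, C, H * W * N)
  for (b in seq_len(f)) {
    for (a in seq_len(f)) {
      lino <- as.integer(outer(a + f * (0:(H - 1L)),
                               (b - 1L + f * (0:(W - 1L))) * Hf, "+"))
      bidx <- as.integer(outer(lino, (seq_len(N) - 1L) * Hf * Wf, "+"))
      dx <- dx + cpp_gather(dym, bidx)
    }
  }
  array(dx, c(C, H * W, N))
}

## ---- temporal collapse ------------------------------------------------------

collapse_f <- function(x, HW, T, N, method) {
  C <- dim(x)[1]
  if (method == "mean") {
    acc <- array(0, c(C, HW, N))
    for (t in seq_len(T)) {
      acc <- acc + x[, ((t - 1L) * HW + 1L):(t * HW), , drop = FALSE]
    }
    list(y = acc / T, arg = NULL)
  } else {
    best <- x[, 1:HW, , drop = FALSE]
    arg <- array(1L, c(C, HW, N))
    for (t in seq(2L, length.out = T - 1L)) {
      sl <- x[, ((t - 1L) * HW + 1L):(t * HW), , drop = FALSE]
      upd <- sl > best
      best[upd] <- sl[upd]
      arg[upd] <- t
    }
    list(y = best, arg = arg)
  }
}

collapse_b <- function(cache, dy, HW, T, N, method) {
  C <- dim(dy)[1]
  dx <- array(0, c(C, HW * T, N))
  if (method == "mean") {
    sl <- dy / T
    for (t in seq_len(T)) dx[, ((t - 1L) * HW + 1L):(t * HW), ] <- sl
  } else {
    for (t in seq_len(T)) {
      sel <- cache$arg == t
      sl <- array(0, c(C, HW, N))
      sl[sel] <- dy[sel]
      dx[, ((t - 1L) * HW + 1L):(t * HW), ] <- sl
    }
  }
  dx
}

## ---- softmax over the class axis -------------------------------------------

softmax_cols <- function(z) {
  K <- nrow(z)
  mx <- z[1, ]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, z[k, ])
  p <- exp(z - rep(mx, each = K))
  s <- colSums(p)
  p * rep(1 / s, each = K)
}
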