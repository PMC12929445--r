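# Split-attention: channels are divided into K cardinal groups, each group
# into r radix branches; branch weights come from a squeeze (global average
# pool) -> dense -> BN -> ReLU -> dense bottleneck, normalized across branches
# with a softmax per channel (r-softmax), and the output is the
# attention-weighted sum of the branches.

#' Split-attention configuration
#'
#' @param radix Number of branches (`r`) the channels are split into.
#' @param cardinality Number of cardinal groups (`K`) processed independently.
#' @param hidden_multiplier Width of the bottleneck dense layer as a multiple
#'   of the per-branch channel count.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(radix = 4L, cardinality = 1L, hidden_multiplier = 2L) {
  radix <- as.integer(radix); cardinality <- as.integer(cardinality)
  stopifnot(radix >= 1L, cardinality >= 1L, hidden_multiplier >= 1L)
  structure(list(radix = radix, cardinality = cardinality,
                 hidden_multiplier = as.integer(hidden_multiplier)),
            class = "sa_config")
}

# core attention over an already-split C = K * r * c input
new_sa_core <- function(C, cfg) {
  r <- cfg$radix; K <- cfg$cardinality
  if (C %% (r * K) != 0L) {
    stop(sprintf(
      "channel count %d is not divisible by radix x cardinality = %d x %d",
      C, r, K))
  }
  c_br <- C %/% (r * K)
  c_hid <- cfg$hidden_multiplier * c_br
  groups <- lapply(seq_len(K), function(k) {
    list(d1 = new_dense(c_br, c_hid, bias = FALSE),
         bn1 = new_bn(c_hid),
         d2 = new_dense(c_hid, r * c_br, init = "zero"))
  })
  list(groups = groups, r = r, K = K, c_br = c_br, c_hid = c_hid, C = C)
}

sa_core_f <- function(core, x, N, train, keep = TRUE) {
  r <- core$r; K <- core$K; c_br <- core$c_br
  HW <- dim(x)[2]
  y <- array(0, c(K * c_br, HW, N))
  gc_list <- vector("list", K)
  for (k in seq_len(K)) {
    g <- core$groups[[k]]
    g0 <- (k - 1L) * r * c_br
    xagg <- array(0, c(c_br, HW, N))
    for (i in seq_len(r)) {
      rows <- g0 + (i - 1L) * c_br + seq_len(c_br)
      xagg <- xagg + x[rows, , , drop = FALSE]
    }
    pool <- colMeans(aperm(xagg, c(2, 1, 3)))          # c_br x N
    pool <- matrix(pool, core$c_br, N)
    z <- g$d1$par$W %*% pool
    bnc <- bn_f(g$bn1, z, train)
    rl <- relu_f(bnc$y)
    lg <- g$d2$par$W %*% matrix(rl$y, core$c_hid, N) + g$d2$par$b
    lga <- array(lg, c(c_br, r, N))
    mx <- matrix(lga[, 1, ], c_br, N)
    if (r > 1) for (i in 2:r) mx <- pmax(mx, matrix(lga[, i, ], c_br, N))
    A <- array(0, c(c_br, r, N))
    s <- matrix(0, c_br, N)
    for (i in seq_len(r)) {
      A[, i, ] <- exp(matrix(lga[, i, ], c_br, N) - mx)
      s <- s + matrix(A[, i, ], c_br, N)
    }
    for (i in seq_len(r)) A[, i, ] <- matrix(A[, i, ], c_br, N) / s
    out_rows <- (k - 1L) * c_br + seq_len(c_br)
    for (n in seq_len(N)) {
      acc <- matrix(0, c_br, HW)
      for (i in seq_len(r)) {
        rows <- g0 + (i - 1L) * c_br + seq_len(c_br)
        acc <- acc + matrix(x[rows, , n], c_br, HW) * A[, i, n]
      }
      y[out_rows, , n] <- acc
    }
    gc_list[[k]] <- if (keep) list(pool = pool, bn = bnc, mask = rl$mask,
                                   h = rl$y, A = A) else list(A = A, pool = pool,
                                                              h = rl$y)
  }
  list(y = y, groups = gc_list)
}

sa_core_b <- function(core, x, cache, dy, N) {
  r <- core$r; K <- core$K; c_br <- core$c_br
  HW <- dim(x)[2]
  dx <- array(0, dim(x))
  for (k in seq_len(K)) {
    g <- core$groups[[k]]
    gcache <- cache$groups[[k]]
    g0 <- (k - 1L) * r * c_br
    out_rows <- (k - 1L) * c_br + seq_len(c_br)
    dyg <- dy[out_rows, , , drop = FALSE]
    A <- gcache$A
    dA <- array(0, c(c_br, r, N))
    for (n in seq_len(N)) {
      dym <- matrix(dyg[, , n], c_br, HW)
      for (i in seq_len(r)) {
        rows <- g0 + (i - 1L) * c_br + seq_len(c_br)
        dx[rows, , n] <- dx[rows, , n] + dym * A[, i, n]
        dA[, i, n] <- rowSums(dym * matrix(x[rows, , n], c_br, HW))
      }
    }
    # softmax backward across the branch axis
    S <- matrix(0, c_br, N)
    for (i in seq_len(r)) S <- S + matrix(A[, i, ] * dA[, i, ], c_br, N)
    dlg <- array(0, c(c_br, r, N))
    for (i in seq_len(r)) {
      dlg[, i, ] <- matrix(A[, i, ], c_br, N) *
        (matrix(dA[, i, ], c_br, N) - S)
    }
    dlgm <- matrix(dlg, r * c_br, N)
    g$d2$grad$W <- g$d2$grad$W + dlgm %*% t(matrix(gcache$h, core$c_hid, N))
    g$d2$grad$b <- g$d2$grad$b + rowSums(dlgm)
    dh <- t(g$d2$par$W) %*% dlgm
    dh <- relu_b(gcache$mask, dh)
    dz <- bn_b(g$bn1, gcache$bn, dh)
    dz <- matrix(dz, core$c_hid, N)
    g$d1$grad$W <- g$d1$grad$W + dz %*% t(gcache$pool)
    dpool <- t(g$d1$par$W) %*% dz / HW                 # spread of the mean
    for (n in seq_len(N)) {
      dagg <- matrix(dpool[, n], c_br, HW)
      for (i in seq_len(r)) {
        rows <- g0 + (i - 1L) * c_br + seq_len(c_br)
        dx[rows, , n] <- dx[rows, , n] + dagg
      }
    }
  }
  dx
}

#' Create a split-attention block
#'
#' The block holds the learnable attention parameters for a fixed input
#' channel count. The input's `C` channels are interpreted as `K` cardinal
#' groups of `r` branches with `c = C/(K*r)` channels each; the output has
#' `K*c` channels (the weighted branch sum per group, groups concatenated).
#'
#' @param channels Input channel count `C`; must be divisible by
#'   `radix * cardinality`.
#' @param config An [sa_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `sa_block`.
#' @export
sa_block <- function(channels, config = sa_config(), seed = 1L) {
  set.seed(as.integer(seed))
  core <- new_sa_core(as.integer(channels), config)
  structure(list(core = core, config = config), class = "sa_block")
}

#' Apply split-attention to a feature map
#'
#' Splits the channels of `features` into radix branches, aggregates them,
#' derives per-branch attention weights through the pooled bottleneck and the
#' r-softmax, and returns the attention-weighted branch sum together with the
#' intermediate quantities (branch aggregate, pooled descriptor, bottleneck
#' output, attention weights).
#'
#' @param features Numeric array of dim `(C, h, w)`.
#' @param block An [sa_block()] whose channel count matches `C`.
#' @param train Logical; use batch statistics in the bottleneck batch norm
#'   (otherwise running statistics).
#' @return A list with `output` (array `(K*c, h, w)`) and `intermediates`
#'   (list with `pool`, `attention` -- array `(c, r, K)` whose branch axis
#'   sums to 1 -- and `bottleneck`).
#' @export
split_attention <- function(features, block, train = FALSE) {
  stopifnot(inherits(block, "sa_block"), length(dim(features)) == 3)
  C <- dim(features)[1]
  if (C != block$core$C) {
    stop(sprintf("block was built for %d channels, features have %d (radix %d, cardinality %d)",
                 block$core$C, C, block$config$radix, block$config$cardinality))
  }
  h <- dim(features)[2]; w <- dim(features)[3]
  x <- array(features, c(C, h * w, 1L))
  res <- sa_core_f(block$core, x, N = 1L, train = train)
  K <- block$core$K; r <- block$core$r; c_br <- block$core$c_br
  att <- array(0, c(c_br, r, K))
  bott <- matrix(0, block$core$c_hid, K)
  pool <- matrix(0, c_br, K)
  for (k in seq_len(K)) {
    att[, , k] <- res$groups[[k]]$A[, , 1]
    bott[, k] <- res$groups[[k]]$h[, 1]
    pool[, k] <- res$groups[[k]]$pool[, 1]
  }
  list(output = array(res$y, c(K * c_br, h, w)),
       intermediates = list(pool = pool, bottleneck = bott, attention = att))
}

# width-preserving pyramid unit: 1x1 conv producing the r*C branch stack,
# followed by the split-attention reduction back to C channels
new_sa_module <- function(C, cfg) {
  list(bconv = new_conv2d(C, C * cfg$radix, k = 1L, bias = TRUE),
       core = new_sa_core(C * cfg$radix, cfg))
}

sa_module_f <- function(mod, x, H, W, N, train) {
  cv <- conv2d_f(mod$bconv, x, H, W, N)
  core <- sa_core_f(mod$core, cv$y, N, train)
  list(y = core$y, branches = cv$y, core_cache = core)
}

sa_module_b <- function(mod, x, cache, dy, H, W, N) {
  dbr <- sa_core_b(mod$core, cache$branches, cache$core_cache, dy, N)
  conv2d_b(mod$bconv, x, dbr, H, W, N)
}
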