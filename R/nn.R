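# Minimal neural-network layer kit.
#
# Conventions: dense activations are (features x batch) matrices;
# convolutional activations are (H, W, C, B) arrays. Layers are plain lists
# with a `type`, a `params` list of weight matrices/vectors, and (for batch
# norm) a `buffers` environment holding running statistics, mutated
# in place during training-mode forwards. Gradients mirror `params`.
# Convolutions use im2col so the inner products run through BLAS.

nn_linear <- function(n_in, n_out) {
  list(type = "linear", n_in = n_in, n_out = n_out,
       params = list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                                n_out, n_in),
                     b = numeric(n_out)))
}

nn_conv <- function(c_in, c_out, k, stride = 1L, pad = 0L) {
  fan_in <- k * k * c_in
  list(type = "conv", c_in = c_in, c_out = c_out, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       params = list(W = matrix(stats::rnorm(c_out * fan_in,
                                             sd = sqrt(2 / fan_in)),
                                c_out, fan_in),
                     b = numeric(c_out)))
}

nn_bn <- function(n, kind = c("1d", "2d"), momentum = 0.1, eps = 1e-5) {
  kind <- match.arg(kind)
  buf <- new.env(parent = emptyenv())
  buf$running_mean <- numeric(n)
  buf$running_var <- rep(1, n)
  list(type = paste0("bn", kind), n = n, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n), beta = numeric(n)), buffers = buf)
}

nn_relu <- function() list(type = "relu", params = NULL)
nn_gap <- function() list(type = "gap", params = NULL)
nn_flatten <- function() list(type = "flatten", params = NULL)
nn_maxpool <- function(k, stride, pad = 0L)
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = NULL)

# ---- im2col machinery ------------------------------------------------------

im2col_idx <- function(Hp, Wp, C, k, stride) {
  out_h <- (Hp - k) %/% stride + 1L
  out_w <- (Wp - k) %/% stride + 1L
  dh <- rep.int(seq_len(k), k * C)
  dw <- rep.int(rep(seq_len(k), each = k), C)
  dc <- rep(seq_len(C), each = k * k)
  off <- (dh - 1L) + Hp * (dw - 1L) + Hp * Wp * (dc - 1L)
  oh <- rep.int(seq_len(out_h), out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  corner <- (oh - 1L) * stride + Hp * ((ow - 1L) * stride)
  list(idx = outer(off, corner, "+") + 1L, out_h = out_h, out_w = out_w)
}

pad4 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  out
}

unpad4 <- function(x, p, dims_in) {
  if (p == 0L) return(x)
  x[p + seq_len(dims_in[1L]), p + seq_len(dims_in[2L]), , , drop = FALSE]
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  if (layer$k == 1L && layer$pad == 0L) return(conv1x1_forward(layer, x))
  xp <- pad4(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_idx(dp[1L], dp[2L], dp[3L], layer$k, layer$stride)
  kkC <- layer$k^2 * dp[3L]
  P <- ii$out_h * ii$out_w
  B <- d[4L]
  xm <- matrix(xp, nrow = dp[1L] * dp[2L] * dp[3L])
  cols <- xm[as.vector(ii$idx), , drop = FALSE]
  dim(cols) <- c(kkC, P * B)
  y <- layer$params$W %*% cols + layer$params$b
  out <- aperm(array(y, c(layer$c_out, ii$out_h, ii$out_w, B)), c(2, 3, 1, 4))
  list(out = out,
       cache = list(cols = cols, idx = ii$idx, dims_p = dp, dims_in = d,
                    out_h = ii$out_h, out_w = ii$out_w))
}

# 1x1 convolution: a per-pixel linear map; skip im2col entirely
conv1x1_forward <- function(layer, x) {
  d <- dim(x)
  s <- layer$stride
  if (s != 1L) {
    x <- x[seq(1L, d[1L], by = s), seq(1L, d[2L], by = s), , , drop = FALSE]
  }
  ds <- dim(x)
  cols <- matrix(aperm(x, c(3, 1, 2, 4)), d[3L])
  y <- layer$params$W %*% cols + layer$params$b
  out <- aperm(array(y, c(layer$c_out, ds[1L], ds[2L], ds[4L])), c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, dims_in = d, dims_s = ds,
                               out_h = ds[1L], out_w = ds[2L], one = TRUE))
}

conv1x1_backward <- function(layer, cache, dout, need_dx = TRUE) {
  dy <- aperm(dout, c(3, 1, 2, 4))
  dim(dy) <- c(layer$c_out, prod(cache$dims_s[c(1, 2, 4)]))
  dW <- tcrossprod(dy, cache$cols)
  db <- rowSums(dy)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$params$W, dy)
    ds <- cache$dims_s
    dxs <- aperm(array(dcols, c(ds[3L], ds[1L], ds[2L], ds[4L])), c(2, 3, 1, 4))
    if (layer$stride == 1L) {
      dx <- dxs
    } else {
      d <- cache$dims_in
      dx <- array(0, d)
      dx[seq(1L, d[1L], by = layer$stride),
         seq(1L, d[2L], by = layer$stride), , ] <- dxs
    }
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

conv_backward <- function(layer, cache, dout, need_dx = TRUE) {
  if (isTRUE(cache$one)) return(conv1x1_backward(layer, cache, dout, need_dx))
  B <- cache$dims_in[4L]
  P <- cache$out_h * cache$out_w
  dy <- aperm(dout, c(3, 1, 2, 4))
  dim(dy) <- c(layer$c_out, P * B)
  dW <- tcrossprod(dy, cache$cols)
  db <- rowSums(dy)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$params$W, dy)
    kkC <- nrow(dcols)
    dim(dcols) <- c(kkC * P, B)
    idxvec <- as.vector(cache$idx)
    rs <- rowsum(dcols, group = idxvec)
    dpm <- matrix(0, prod(cache$dims_p[1:3]), B)
    dpm[as.integer(rownames(rs)), ] <- rs
    dx <- unpad4(array(dpm, c(cache$dims_p[1:3], B)), layer$pad, cache$dims_in)
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  xp <- pad4(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_idx(dp[1L], dp[2L], 1L, layer$k, layer$stride)
  xm <- matrix(xp, dp[1L] * dp[2L], d[3L] * d[4L])
  cols <- xm[as.vector(ii$idx), , drop = FALSE]
  kk <- layer$k^2
  P <- ii$out_h * ii$out_w
  carr <- array(cols, c(kk, P, d[3L] * d[4L]))
  res <- carr[1L, , ]
  for (j in seq_len(kk)[-1L]) res <- pmax(res, carr[j, , ])
  list(out = array(res, c(ii$out_h, ii$out_w, d[3L], d[4L])), cache = NULL)
}

# ---- batch norm ------------------------------------------------------------

bn_core_forward <- function(layer, xm, train) {
  buf <- layer$buffers
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    m <- layer$momentum
    buf$running_mean <- (1 - m) * buf$running_mean + m * mu
    buf$running_var <- (1 - m) * buf$running_var + m * va
  } else {
    mu <- buf$running_mean
    va <- buf$running_var
  }
  istd <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
               layer$params$beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, train = train))
}

bn_core_backward <- function(layer, cache, dout) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, layer$params$gamma, "*")
  if (cache$train) {
    N <- nrow(xhat)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$istd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$istd, "*")
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- generic sequential dispatch -------------------------------------------

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    linear = list(out = layer$params$W %*% x + layer$params$b,
                  cache = list(x = x)),
    conv = conv_forward(layer, x),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    bn1d = {
      r <- bn_core_forward(layer, t(x), train)
      list(out = t(r$out), cache = r$cache)
    },
    bn2d = {
      d <- dim(x)
      if (!train) {
        # eval mode is a fixed per-channel affine map; no reshuffling needed
        buf <- layer$buffers
        istd <- 1 / sqrt(buf$running_var + layer$eps)
        sc <- layer$params$gamma * istd
        sh <- layer$params$beta - buf$running_mean * sc
        xm <- x
        dim(xm) <- c(d[1L] * d[2L], d[3L] * d[4L])
        out <- sweep(sweep(xm, 2L, rep(sc, d[4L]), "*"), 2L,
                     rep(sh, d[4L]), "+")
        dim(out) <- d
        list(out = out, cache = list(istd = istd, train = FALSE, dims = d,
                                     affine = TRUE,
                                     xhat = NULL))
      } else {
        xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3L])
        r <- bn_core_forward(layer, xm, train)
        list(out = aperm(array(r$out, c(d[1L], d[2L], d[4L], d[3L])),
                         c(1, 2, 4, 3)),
             cache = c(r$cache, list(dims = d)))
      }
    },
    gap = {
      d <- dim(x)
      cm <- colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L]))
      list(out = matrix(cm, d[3L], d[4L]), cache = list(dims = d))
    },
    flatten = {
      d <- dim(x)
      dim(x) <- c(prod(d[1:3]), d[4L])
      list(out = x, cache = list(dims = d))
    },
    maxpool = maxpool_forward(layer, x),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    linear = list(
      dx = if (need_dx) crossprod(layer$params$W, dout),
      grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout))),
    conv = conv_backward(layer, cache, dout, need_dx),
    relu = list(dx = dout * cache$mask, grads = NULL),
    bn1d = {
      r <- bn_core_backward(layer, cache, t(dout))
      list(dx = t(r$dx), grads = r$grads)
    },
    bn2d = {
      if (isTRUE(cache$affine))
        stop("eval-mode bn2d is forward-only (frozen-encoder use)")
      d <- cache$dims
      dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3L])
      r <- bn_core_backward(layer, cache, dm)
      list(dx = aperm(array(r$dx, c(d[1L], d[2L], d[4L], d[3L])),
                      c(1, 2, 4, 3)),
           grads = r$grads)
    },
    gap = {
      d <- cache$dims
      n <- d[1L] * d[2L]
      dxm <- matrix(rep(as.vector(dout) / n, each = n), n, d[3L] * d[4L])
      list(dx = array(dxm, d), grads = NULL)
    },
    flatten = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = NULL)
    },
    maxpool = stop("maxpool has no backward pass (frozen-encoder use only)"),
    stop("unknown layer type: ", layer$type))
}

seq_forward <- function(layers, x, train = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    need_dx <- need_input_grad || i > 1L
    r <- layer_backward(layers[[i]], caches[[i]], dout, need_dx)
    grads[i] <- list(r$grads)  # [[<-]] with NULL would drop the slot
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

# Deep copy of a layer stack, duplicating batch-norm buffer environments so
# checkpoints do not alias the live model's running statistics.
clone_layers <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$buffers)) {
      buf <- new.env(parent = emptyenv())
      buf$running_mean <- l$buffers$running_mean
      buf$running_var <- l$buffers$running_var
      l$buffers <- buf
    }
    l
  })
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

# One Adam update (default torch hyperparameters) for a layer stack;
# `t` is the shared global step for bias correction.
adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Accumulate two gradient lists of identical shape (NULL-safe).
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    if (is.null(b[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(g, s) {
  lapply(g, function(l) if (is.null(l)) NULL else lapply(l, function(p) p * s))
}
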