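# Minimal functional layer framework backing the model zoo.
#
# Every layer is a plain list: type, name, params (trainable arrays), buffers
# (non-trainable state, e.g. batch-norm running moments) and cfg. Internal
# tensor layout is (feature maps, channels, time, batch), column-major, so a
# matrix(x, nrow = maps) view puts one feature map per row.
#
# layer_forward(layer, x, training)  -> list(out, cache, layer)
# layer_backward(layer, x, cache, d) -> list(dx, grads)   # grads named as params

conv_pads <- function(kh, kw, pad) {
  if (pad == "valid") return(c(0L, 0L, 0L, 0L))
  c((kh - 1L) %/% 2L, (kh - 1L) - (kh - 1L) %/% 2L,
    (kw - 1L) %/% 2L, (kw - 1L) - (kw - 1L) %/% 2L)
}

# Glorot-uniform init; consumes the ambient RNG stream (seeded by the caller)
glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

layer_conv <- function(name, in_maps, out_maps, kh, kw, pad = "valid",
                       groups = 1L, bias = TRUE) {
  cig <- in_maps %/% groups
  fan_in <- cig * kh * kw
  fan_out <- (out_maps %/% groups) * kh * kw
  list(type = "conv", name = name,
       params = list(W = glorot(c(out_maps, cig, kh, kw), fan_in, fan_out),
                     b = if (bias) numeric(out_maps) else NULL),
       buffers = list(),
       cfg = list(groups = as.integer(groups), pad = pad,
                  pads = conv_pads(kh, kw, pad), kh = kh, kw = kw,
                  use_bias = bias))
}

layer_enk <- function(name, params) {
  stopifnot(inherits(params, "enk_params"))
  p <- list(w = params$w, b = params$b, K = params$K)
  if (!params$shared_affine) { p$w_s <- params$w_s; p$b_s <- params$b_s }
  list(type = "enk", name = name, params = p, buffers = list(),
       cfg = list(shared_affine = params$shared_affine, l = params$l,
                  m = params$m, k = params$k, trainable = params$trainable))
}

layer_batchnorm <- function(name, maps, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", name = name,
       params = list(gamma = rep(1, maps), beta = numeric(maps)),
       buffers = list(mean = numeric(maps), var = rep(1, maps)),
       cfg = list(momentum = momentum, eps = eps))
}

layer_activation <- function(name, fun) {
  stopifnot(fun %in% c("elu", "relu", "square", "safelog"))
  list(type = "activation", name = name, params = list(), buffers = list(),
       cfg = list(fun = fun))
}

layer_pool <- function(name, mode, size, stride = size) {
  stopifnot(mode %in% c("avg", "max"))
  list(type = "pool", name = name, params = list(), buffers = list(),
       cfg = list(mode = mode, size = as.integer(size), stride = as.integer(stride)))
}

layer_dropout <- function(name, p) {
  list(type = "dropout", name = name, params = list(), buffers = list(),
       cfg = list(p = p))
}

layer_dense <- function(name, in_features, n_out) {
  list(type = "dense", name = name,
       params = list(W = glorot(c(n_out, in_features), in_features, n_out),
                     b = numeric(n_out)),
       buffers = list(), cfg = list(in_features = as.integer(in_features)))
}

# Recurrent convolutional layer (weight-shared unrolling): the feed-forward
# response conv(x, Wf) is computed once and re-injected at every iteration,
# h_0 = relu(ff), h_i = relu(ff + conv(h_{i-1}, Wr)).
layer_rcl <- function(name, maps, k_ff = 3L, k_rec = 3L, iterations = 3L) {
  fan <- maps * k_ff
  list(type = "rcl", name = name,
       params = list(Wf = glorot(c(maps, maps, 1L, k_ff), fan, fan),
                     bf = numeric(maps),
                     Wr = glorot(c(maps, maps, 1L, k_rec), maps * k_rec, maps * k_rec) * 0.5),
       buffers = list(),
       cfg = list(iterations = as.integer(iterations),
                  pads_f = conv_pads(1L, k_ff, "same"),
                  pads_r = conv_pads(1L, k_rec, "same"),
                  k_ff = k_ff, k_rec = k_rec))
}

act_fwd <- function(fun, x) {
  switch(fun,
    elu = ifelse(x > 0, x, exp(x) - 1),
    relu = pmax(x, 0),
    square = x * x,
    safelog = log(pmax(x, 1e-6)))
}

act_bwd <- function(fun, x, out, d) {
  switch(fun,
    elu = d * ifelse(x > 0, 1, out + 1),
    relu = d * (x > 0),
    square = d * 2 * x,
    safelog = d * ifelse(x > 1e-6, 1 / x, 0))
}

layer_forward <- function(layer, x, training = FALSE) {
  t <- layer$type
  if (t == "conv") {
    pd <- layer$cfg$pads
    bias <- layer$params$b %||% numeric(dim(layer$params$W)[1])
    y <- cpp_conv2d(x, layer$params$W, bias, pd[1], pd[2], pd[3], pd[4],
                    layer$cfg$groups)
    return(list(out = y, cache = NULL, layer = layer))
  }
  if (t == "enk") {
    ep <- structure(c(layer$params,
                      list(shared_affine = layer$cfg$shared_affine,
                           trainable = layer$cfg$trainable,
                           k = layer$cfg$k, l = layer$cfg$l, m = layer$cfg$m)),
                    class = "enk_params")
    dec <- enk_fwd_internal(x, ep)
    return(list(out = dec$Y, cache = list(dec = dec, ep = ep), layer = layer))
  }
  if (t == "batchnorm") {
    M <- dim(x)[1]
    xm <- matrix(x, nrow = M)
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu * mu
      mom <- layer$cfg$momentum
      layer$buffers$mean <- (1 - mom) * layer$buffers$mean + mom * mu
      layer$buffers$var <- (1 - mom) * layer$buffers$var + mom * v
    } else {
      mu <- layer$buffers$mean
      v <- layer$buffers$var
    }
    ivar <- 1 / sqrt(v + layer$cfg$eps)
    xhat <- (xm - mu) * ivar
    y <- array(layer$params$gamma * xhat + layer$params$beta, dim(x))
    return(list(out = y, cache = list(xhat = xhat, ivar = ivar, training = training),
                layer = layer))
  }
  if (t == "activation") {
    return(list(out = act_fwd(layer$cfg$fun, x), cache = NULL, layer = layer))
  }
  if (t == "pool") {
    d <- dim(x)
    size <- layer$cfg$size; stride <- layer$cfg$stride
    To <- (d[3] - size) %/% stride + 1L
    if (To < 1L) stop("pooling window ", size, " does not fit ", d[3], " samples", call. = FALSE)
    starts <- (seq_len(To) - 1L) * stride + 1L
    if (layer$cfg$mode == "avg") {
      acc <- array(0, c(d[1], d[2], To, d[4]))
      for (off in 0:(size - 1L))
        acc <- acc + x[, , starts + off, , drop = FALSE]
      return(list(out = acc / size, cache = list(To = To, starts = starts),
                  layer = layer))
    }
    cur <- array(-Inf, c(d[1], d[2], To, d[4]))
    arg <- array(0L, c(d[1], d[2], To, d[4]))
    for (off in 0:(size - 1L)) {
      xo <- x[, , starts + off, , drop = FALSE]
      upd <- xo > cur
      cur[upd] <- xo[upd]
      arg[upd] <- off
    }
    return(list(out = cur, cache = list(To = To, starts = starts, arg = arg),
                layer = layer))
  }
  if (t == "dropout") {
    if (!training || layer$cfg$p <= 0)
      return(list(out = x, cache = list(mask = NULL), layer = layer))
    keep <- 1 - layer$cfg$p
    mask <- array((stats::runif(length(x)) < keep) / keep, dim(x))
    return(list(out = x * mask, cache = list(mask = mask), layer = layer))
  }
  if (t == "dense") {
    B <- dim(x)[4]
    xm <- matrix(x, ncol = B)
    y <- layer$params$W %*% xm + layer$params$b
    return(list(out = y, cache = list(in_dim = dim(x)), layer = layer))
  }
  if (t == "rcl") {
    pf <- layer$cfg$pads_f; pr <- layer$cfg$pads_r
    maps <- dim(layer$params$Wf)[1]
    ff <- cpp_conv2d(x, layer$params$Wf, layer$params$bf, pf[1], pf[2], pf[3], pf[4], 1L)
    hs <- vector("list", layer$cfg$iterations + 1L)
    pre <- ff
    hs[[1]] <- pmax(pre, 0)
    pres <- vector("list", layer$cfg$iterations + 1L)
    pres[[1]] <- NULL  # mask recoverable from hs
    for (i in seq_len(layer$cfg$iterations)) {
      pre <- ff + cpp_conv2d(hs[[i]], layer$params$Wr, numeric(maps),
                             pr[1], pr[2], pr[3], pr[4], 1L)
      hs[[i + 1L]] <- pmax(pre, 0)
    }
    return(list(out = hs[[layer$cfg$iterations + 1L]],
                cache = list(hs = hs), layer = layer))
  }
  stop("unknown layer type: ", t)
}

layer_backward <- function(layer, x, cache, d) {
  t <- layer$type
  if (t == "conv") {
    pd <- layer$cfg$pads
    dx <- cpp_conv2d_grad_input(d, layer$params$W, dim(x)[2], dim(x)[3],
                                pd[1], pd[2], pd[3], pd[4], layer$cfg$groups)
    dW <- cpp_conv2d_grad_weights(x, d, layer$cfg$kh, layer$cfg$kw,
                                  pd[1], pd[2], pd[3], pd[4], layer$cfg$groups)
    grads <- list(W = dW)
    if (layer$cfg$use_bias) grads$b <- rowSums(matrix(d, nrow = dim(d)[1]))
    return(list(dx = dx, grads = grads))
  }
  if (t == "enk") {
    g <- enk_bwd_internal(x, cache$ep, cache$dec, d)
    grads <- list(w = g$dw, b = g$db, K = g$dK)
    if (!cache$ep$shared_affine) { grads$w_s <- g$dw_s; grads$b_s <- g$db_s }
    if (!isTRUE(layer$cfg$trainable)) grads <- lapply(grads, function(a) a * 0)
    return(list(dx = g$dx, grads = grads))
  }
  if (t == "batchnorm") {
    M <- dim(x)[1]
    dm <- matrix(d, nrow = M)
    xhat <- cache$xhat; ivar <- cache$ivar
    dgamma <- rowSums(dm * xhat)
    dbeta <- rowSums(dm)
    if (cache$training) {
      N <- ncol(dm)
      dxhat <- dm * layer$params$gamma
      dx <- ivar / N * (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      dx <- array(dx, dim(x))
    } else {
      dx <- array(dm * layer$params$gamma * ivar, dim(x))
    }
    return(list(dx = dx, grads = list(gamma = dgamma, beta = dbeta)))
  }
  if (t == "activation") {
    out <- act_fwd(layer$cfg$fun, x)  # cheap; avoids caching
    return(list(dx = act_bwd(layer$cfg$fun, x, out, d), grads = list()))
  }
  if (t == "pool") {
    size <- layer$cfg$size
    starts <- cache$starts
    dx <- array(0, dim(x))
    if (layer$cfg$mode == "avg") {
      dd <- d / size
      for (off in 0:(size - 1L))
        dx[, , starts + off, ] <- dx[, , starts + off, , drop = FALSE] + dd
    } else {
      for (off in 0:(size - 1L)) {
        m <- d * (cache$arg == off)
        dx[, , starts + off, ] <- dx[, , starts + off, , drop = FALSE] + m
      }
    }
    return(list(dx = dx, grads = list()))
  }
  if (t == "dropout") {
    if (is.null(cache$mask)) return(list(dx = d, grads = list()))
    return(list(dx = d * cache$mask, grads = list()))
  }
  if (t == "dense") {
    B <- tail(cache$in_dim, 1)
    xm <- matrix(x, ncol = B)
    dW <- d %*% t(xm)
    db <- rowSums(d)
    dx <- array(t(layer$params$W) %*% d, cache$in_dim)
    return(list(dx = dx, grads = list(W = dW, b = db)))
  }
  if (t == "rcl") {
    pf <- layer$cfg$pads_f; pr <- layer$cfg$pads_r
    hs <- cache$hs
    iters <- layer$cfg$iterations
    maps <- dim(layer$params$Wf)[1]
    dh <- d
    dff <- array(0, dim(d))
    dWr <- array(0, dim(layer$params$Wr))
    for (i in seq(iters, 1L)) {
      dpre <- dh * (hs[[i + 1L]] > 0)
      dff <- dff + dpre
      dWr <- dWr + cpp_conv2d_grad_weights(hs[[i]], dpre, 1L, layer$cfg$k_rec,
                                           pr[1], pr[2], pr[3], pr[4], 1L)
      dh <- cpp_conv2d_grad_input(dpre, layer$params$Wr,
                                  dim(d)[2], dim(d)[3],
                                  pr[1], pr[2], pr[3], pr[4], 1L)
    }
    dpre0 <- dh * (hs[[1L]] > 0)
    dff <- dff + dpre0
    dWf <- cpp_conv2d_grad_weights(x, dff, 1L, layer$cfg$k_ff,
                                   pf[1], pf[2], pf[3], pf[4], 1L)
    dbf <- rowSums(matrix(dff, nrow = maps))
    dx <- cpp_conv2d_grad_input(dff, layer$params$Wf, dim(x)[2], dim(x)[3],
                                pf[1], pf[2], pf[3], pf[4], 1L)
    return(list(dx = dx, grads = list(Wf = dWf, bf = dbf, Wr = dWr)))
  }
  stop("unknown layer type: ", t)
}
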