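# Independent scalar triple-loop implementation of the EnK decomposition,
# written directly from the component definitions (affine -> sine ->
# multiplicative seasonal -> sliding-window artifact sum, first sample
# passes the plain affine). Used as the oracle against the vectorized path.
enk_oracle <- function(x, w, b, K, w_s = NULL, b_s = NULL) {
  d <- dim(x); B <- d[1]; M <- d[2]; C <- d[3]; Tn <- d[4]
  l <- nrow(K); m <- ncol(K)
  ph_lo <- (l - 1) %/% 2
  pw <- (m - 1) %/% 2
  Y <- array(0, d)
  for (bb in 1:B) for (mm in 1:M) {
    A <- matrix(0, C, Tn)
    for (cc in 1:C) for (tt in 1:Tn) {
      acc <- 0
      for (i in 1:l) for (j in 1:m) {
        ci <- cc + (i - 1) - ph_lo
        ti <- tt + (j - 1) - pw
        if (ci >= 1 && ci <= C && ti >= 1 && ti <= Tn)
          acc <- acc + x[bb, mm, ci, ti] * K[i, j]
      }
      A[cc, tt] <- acc
    }
    for (cc in 1:C) for (tt in 1:Tn) {
      z <- w[tt] * x[bb, mm, cc, tt] + b[tt]
      p <- sin(z)
      zs <- if (is.null(w_s)) z else w_s[tt] * x[bb, mm, cc, tt] + b_s[tt]
      Y[bb, mm, cc, tt] <- if (tt == 1) z else p + zs * p + A[cc, tt]
    }
  }
  Y
}

# central finite-difference gradient of f at x (numeric array), elementwise
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    g[j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(1e-8, abs(a) + abs(b))
}

# tiny linearly separable epoch set: class 1 carries a square bump
toy_epochs <- function(n_per_class = 10L, C = 3L, Tn = 32L, amp = 3,
                       noise = 0.5, seed = 11L) {
  set.seed(seed)
  n <- 2L * n_per_class
  dat <- array(rnorm(n * C * Tn, sd = noise), c(n, C, Tn))
  labels <- rep(0:1, each = n_per_class)
  for (e in which(labels == 1L)) dat[e, , 9:16] <- dat[e, , 9:16] + amp
  epoch_set(dat, labels, sampling_rate = 32,
            channel_names = paste0("ch", seq_len(C)))
}

# flatten per-layer grads into the "<layer>.<param>" key scheme
flatten_grads <- function(grads) {
  out <- list()
  for (i in seq_along(grads))
    for (nm in names(grads[[i]]))
      out[[paste0(i, ".", nm)]] <- grads[[i]][[nm]]
  out
}

# analytic + numeric network gradients on a frozen batch (inference mode so
# batch-norm statistics stay fixed during the finite-difference sweep)
network_gradcheck <- function(net, x, y, n_per_param = 2L, eps = 1e-5,
                              seed = 99L) {
  lossfn <- function(nn) {
    probs <- enkit:::softmax_cols(enkit:::net_forward(nn, x)$logits)
    enkit:::cross_entropy(probs, y)
  }
  fwd <- enkit:::net_forward(net, x, training = FALSE, keep = TRUE)
  probs <- enkit:::softmax_cols(fwd$logits)
  onehot <- matrix(0, nrow(probs), ncol(probs))
  onehot[cbind(y + 1L, seq_along(y))] <- 1
  bk <- enkit:::net_backward(net, fwd$xs, fwd$caches,
                             (probs - onehot) / length(y))
  gflat <- flatten_grads(bk$grads)
  flat <- enkit:::collect_params(net)
  set.seed(seed)
  worst <- 0
  for (key in names(flat)) {
    p <- flat[[key]]
    for (j in sample(length(p), min(n_per_param, length(p)))) {
      f2 <- flat
      f2[[key]][j] <- p[j] + eps
      lp <- lossfn(enkit:::set_params(net, f2))
      f2[[key]][j] <- p[j] - eps
      lm <- lossfn(enkit:::set_params(net, f2))
      worst <- max(worst, rel_err((lp - lm) / (2 * eps), gflat[[key]][j]))
    }
  }
  worst
}
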