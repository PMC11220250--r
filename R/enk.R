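#' Encoding-kernel (EnK) parameters
#'
#' Creates the trainable parameter set of one EnK layer: a per-time-step
#' affine transform (weights `w`, biases `b`, both of length `k`) feeding the
#' periodic and seasonal components, and an `l x m` artifact kernel `K`
#' applied as a smoothing convolution over the (channel, time) plane. With
#' the default shared affine the layer adds `2k + l*m` trainable values;
#' with separate affines for the periodic and seasonal terms, `4k + l*m`.
#'
#' The default initialization is a near-pass-through: `w = 1`, `b = 0` and a
#' uniform averaging kernel with entries `1/(l*m)`, so that an untrained EnK
#' perturbs its host network minimally. `init = "random"` draws small
#' Gaussian perturbations around those values (seeded), for experiments on
#' initialization sensitivity.
#'
#' @param k Number of time samples the layer is applied to (`k >= 1`).
#' @param n Channel count of the incoming tensor, used to validate `l`
#'   (optional; `l <= n` must hold at application time regardless).
#' @param l,m Artifact kernel dimensions (rows over channels, columns over
#'   time); `m` must be odd so the time padding is symmetric.
#' @param shared_affine If `TRUE` (default) the periodic and seasonal
#'   components reuse one affine `w, b`; if `FALSE` the seasonal component
#'   gets its own `w_s, b_s`.
#' @param trainable Whether the parameters take gradient updates.
#' @param init `"passthrough"` (default) or `"random"`.
#' @param seed Integer seed, used only for `init = "random"`.
#' @return An object of class `enk_params`.
#' @examples
#' p <- enk_params(k = 16, l = 1, m = 7)
#' length(p$w)            # 16
#' sum(p$K)               # 1 (averaging kernel)
#' @export
enk_params <- function(k, n = NULL, l = 1L, m = 7L, shared_affine = TRUE,
                       trainable = TRUE, init = c("passthrough", "random"),
                       seed = NULL) {
  init <- match.arg(init)
  k <- as.integer(k); l <- as.integer(l); m <- as.integer(m)
  if (k < 1L) stop("k must be >= 1, got ", k, call. = FALSE)
  if (l < 1L || m < 1L) stop("kernel dimensions must be >= 1, got l=", l, ", m=", m, call. = FALSE)
  if (m %% 2L == 0L) stop("artifact kernel width m must be odd for symmetric padding, got m=", m, call. = FALSE)
  if (!is.null(n) && l > n) stop("artifact kernel rows l=", l, " exceed channel count n=", n, call. = FALSE)
  p <- list(
    w = rep(1, k), b = rep(0, k),
    K = matrix(1 / (l * m), l, m),
    shared_affine = isTRUE(shared_affine),
    trainable = isTRUE(trainable),
    k = k, l = l, m = m
  )
  if (!p$shared_affine) { p$w_s <- rep(1, k); p$b_s <- rep(0, k) }
  if (init == "random") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    p$w <- p$w + stats::rnorm(k, 0, 0.05)
    p$b <- p$b + stats::rnorm(k, 0, 0.05)
    p$K <- p$K + matrix(stats::rnorm(l * m, 0, 0.05 / (l * m)), l, m)
    if (!p$shared_affine) {
      p$w_s <- p$w_s + stats::rnorm(k, 0, 0.05)
      p$b_s <- p$b_s + stats::rnorm(k, 0, 0.05)
    }
  }
  structure(p, class = "enk_params")
}

#' @export
print.enk_params <- function(x, ...) {
  cat("EnK parameters: k =", x$k, "time steps, kernel", x$l, "x", x$m,
      if (x$shared_affine) "(shared affine)" else "(separate affines)", "\n")
  cat("  trainable values:", enk_n_params(x), "\n")
  invisible(x)
}

enk_n_params <- function(p) {
  (if (p$shared_affine) 2L else 4L) * p$k + p$l * p$m
}

#' Per-time-step affine transform
#'
#' Applies `Z[..., t] = w[t] * X[..., t] + b[t]`, broadcasting one weight and
#' one bias per time sample across the batch, feature-map and channel axes.
#' This is the pre-activation inside the periodic and seasonal components.
#'
#' @param x Signal tensor (any form accepted by [as_signal_tensor()]).
#' @param w,b Numeric vectors of length equal to the tensor's time axis.
#' @return A tensor of the same shape as `x`.
#' @export
affine_time <- function(x, w, b) {
  x <- as_signal_tensor(x)
  k <- dim(x)[4]
  if (length(w) != k || length(b) != k)
    stop("affine length mismatch: time axis has ", k, " samples but length(w)=",
         length(w), ", length(b)=", length(b), call. = FALSE)
  sweep(sweep(x, 4L, w, `*`), 4L, b, `+`)
}

#' Periodic component
#'
#' The elementwise sine of the pre-activation: the layer's representation of
#' band-limited rhythmic activity. Values are bounded in `[-1, 1]`.
#'
#' @param z Pre-activation tensor (output of [affine_time()]).
#' @return `sin(z)`, same shape.
#' @export
periodic_component <- function(z) {
  if (!all(is.finite(z))) stop("pre-activation contains non-finite values", call. = FALSE)
  sin(z)
}

#' Seasonal component
#'
#' The pre-activation multiplied elementwise by the periodic component,
#' `S = Z * P`, giving the slowly varying term a non-constant variance.
#' Satisfies `|S| <= |Z|` since `|P| <= 1`.
#'
#' @param z Pre-activation tensor.
#' @param p Periodic tensor of identical shape.
#' @return `z * p`, same shape.
#' @export
seasonal_component <- function(z, p) {
  if (!identical(dim(z), dim(p)))
    stop("shape mismatch between pre-activation (", paste(dim(z), collapse = "x"),
         ") and periodic component (", paste(dim(p), collapse = "x"), ")", call. = FALSE)
  z * p
}

# padding for an l x m kernel: symmetric in time (m odd), floor/ceil over rows
kernel_pads <- function(l, m) {
  c(ph_lo = (l - 1L) %/% 2L, ph_hi = (l - 1L) - (l - 1L) %/% 2L,
    pw = (m - 1L) %/% 2L)
}

# internal-layout artifact convolution: x (M, C, T, B), K (l x m), per map
artifact_internal <- function(x, K) {
  M <- dim(x)[1]
  l <- nrow(K); m <- ncol(K)
  if (m %% 2L == 0L) stop("artifact kernel width m must be odd, got ", m, call. = FALSE)
  if (l > dim(x)[2]) stop("artifact kernel rows l=", l, " exceed channel count n=", dim(x)[2], call. = FALSE)
  W <- array(rep(as.numeric(K), each = M), c(M, 1L, l, m))
  pd <- kernel_pads(l, m)
  cpp_conv2d(x, W, numeric(M), pd[1], pd[2], pd[3], pd[3], M)
}

#' Artifact component
#'
#' Sliding 2-D cross-correlation of the raw input with the `l x m` kernel
#' over the (channel, time) plane, zero-padded so the output keeps the input
#' shape, applied independently per batch item and feature map. With the
#' default averaging kernel this is a denoising smoother standing in for a
#' band-pass filtering step.
#'
#' @param x Signal tensor.
#' @param K Numeric `l x m` kernel matrix (`m` odd, `l` at most the channel
#'   count).
#' @return A tensor of the same shape as `x`.
#' @export
artifact_component <- function(x, K) {
  x <- as_signal_tensor(x)
  if (is.null(dim(K))) K <- matrix(K, nrow = 1L)
  from_internal(artifact_internal(to_internal(x), K))
}

#' EnK forward pass: additive time decomposition
#'
#' Decomposes a signal tensor into periodic (`P = sin(Z)`), seasonal
#' (`S = Z * P`) and artifact (`A`, smoothing convolution of the raw input)
#' components, where `Z` is the per-time-step affine pre-activation, and
#' combines them additively: `Y[..., t] = P + S + A` for `t >= 1`, while the
#' first time sample passes through the plain affine, `Y[..., 0] = Z[..., 0]`.
#' The output keeps the input shape exactly, so the layer can be spliced
#' into a convolutional network without disturbing downstream shapes.
#'
#' @param x Signal tensor (any form accepted by [as_signal_tensor()]).
#' @param params An [enk_params()] object consistent with `x` (affine length
#'   equals the time axis; kernel rows at most the channel count).
#' @return An object of class `enk_decomposition`: list with tensors `Z`,
#'   `P`, `S`, `A`, `Y`, all of the input shape (for non-shared affines also
#'   `Z_s`, the seasonal pre-activation).
#' @examples
#' p <- enk_params(k = 2, l = 1, m = 1)
#' d <- enk_forward(c(1, 2), p)
#' d$Y  # [1, 3*sin(2) + 2]
#' @export
enk_forward <- function(x, params) {
  stopifnot(inherits(params, "enk_params"))
  x <- as_signal_tensor(x)
  k <- dim(x)[4]
  if (params$k != k)
    stop("EnK affine length ", params$k, " does not match time axis length ", k, call. = FALSE)
  xi <- to_internal(x)
  dec <- enk_fwd_internal(xi, params)
  out <- lapply(dec[c("Z", "P", "S", "A", "Y", "Z_s")], function(t)
    if (is.null(t)) NULL else from_internal(t))
  out <- out[!vapply(out, is.null, logical(1))]
  structure(c(out, list(params = params)), class = "enk_decomposition")
}

#' @export
print.enk_decomposition <- function(x, ...) {
  d <- dim(x$Y)
  cat("EnK decomposition of a (", paste(d, collapse = ", "), ") tensor\n", sep = "")
  cat("  components: Z (affine), P (periodic), S (seasonal), A (artifact), Y (combined)\n")
  cat("  range(P): [", paste(signif(range(x$P), 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# internal layout forward; returns components plus cache pieces for backward
enk_fwd_internal <- function(x, params) {
  dm <- dim(x)
  w <- params$w; b <- params$b
  wz <- array(rep(w, each = dm[1] * dm[2]), dm)
  Z <- wz * x + array(rep(b, each = dm[1] * dm[2]), dm)
  P <- sin(Z)
  if (params$shared_affine) {
    Zs <- Z
  } else {
    Zs <- array(rep(params$w_s, each = dm[1] * dm[2]), dm) * x +
      array(rep(params$b_s, each = dm[1] * dm[2]), dm)
  }
  S <- Zs * P
  A <- artifact_internal(x, params$K)
  Y <- P + S + A
  Y[, , 1L, ] <- Z[, , 1L, ]   # t = 0 branch wins: plain affine only
  list(Z = Z, P = P, S = S, A = A, Y = Y,
       Z_s = if (params$shared_affine) NULL else Zs)
}

# Backward through the EnK layer (internal layout).
# x, dec from enk_fwd_internal; dY same shape. Returns dx plus parameter
# gradients (dw, db, dK, and dw_s/db_s when affines are separate).
enk_bwd_internal <- function(x, params, dec, dY) {
  dm <- dim(x)
  M <- dm[1]; C <- dm[2]; Tn <- dm[3]; B <- dm[4]
  Z <- dec$Z; P <- dec$P
  Zs <- if (params$shared_affine) Z else dec$Z_s
  cosZ <- cos(Z)
  # t >= 1 rows receive P + S + A; the first time sample only the affine
  dY1 <- dY
  dY1[, , 1L, ] <- 0
  if (params$shared_affine) {
    dZ <- dY1 * (cosZ * (1 + Zs) + P)
    dZ[, , 1L, ] <- dY[, , 1L, ]                 # t = 0: dY/dZ = 1
    dZs <- NULL
  } else {
    dZ <- dY1 * (cosZ * (1 + Zs))
    dZ[, , 1L, ] <- dY[, , 1L, ]
    dZs <- dY1 * P
  }
  # artifact path: grad w.r.t. input and shared kernel
  l <- params$l; m <- params$m
  pd <- kernel_pads(l, m)
  Wrep <- array(rep(as.numeric(params$K), each = M), c(M, 1L, l, m))
  dx_conv <- cpp_conv2d_grad_input(dY1, Wrep, C, Tn, pd[1], pd[2], pd[3], pd[3], M)
  dWrep <- cpp_conv2d_grad_weights(x, dY1, l, m, pd[1], pd[2], pd[3], pd[3], M)
  dK <- matrix(colSums(matrix(dWrep, nrow = M)), l, m)

  wz <- array(rep(params$w, each = M * C), dm)
  dx <- wz * dZ + dx_conv
  # reduce (M, C, ., B) out, keep time
  sum_t <- function(a) colSums(matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = Tn))
  dw <- sum_t(dZ * x)
  db <- sum_t(dZ)
  out <- list(dx = dx, dw = dw, db = db, dK = dK)
  if (!params$shared_affine) {
    dx <- dx + array(rep(params$w_s, each = M * C), dm) * dZs
    out$dx <- dx
    out$dw_s <- sum_t(dZs * x)
    out$db_s <- sum_t(dZs)
  }
  out
}
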