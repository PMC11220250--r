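test_that("per-time-step affine matches elementary arithmetic and validates lengths", {
  expect_equal(as.vector(affine_time(c(1, 2), c(1, 1), c(0, 0))), c(1, 2))
  expect_equal(as.vector(affine_time(c(5, 7), c(0, 0), c(3, 3))), c(3, 3))
  expect_equal(as.vector(affine_time(c(1, 2), c(2, 3), c(1, -1))), c(3, 5))
  err <- tryCatch(affine_time(c(1, 2, 3), c(1, 1), c(0, 0)), error = identity)
  expect_match(conditionMessage(err), "3")
  expect_match(conditionMessage(err), "2")
})

test_that("periodic component is the elementwise sine, bounded in [-1, 1]", {
  expect_equal(periodic_component(0), 0)
  expect_equal(periodic_component(pi / 2), 1)
  expect_equal(periodic_component(2), sin(2), tolerance = 1e-12)
  expect_error(periodic_component(c(1, NA)), "non-finite")
  z <- array(rnorm(200, sd = 10), c(1, 2, 10, 10))
  expect_true(all(abs(periodic_component(z)) <= 1))
})

test_that("seasonal component multiplies affine by periodic and is dominated by |Z|", {
  expect_equal(seasonal_component(0, 0), 0)
  expect_equal(seasonal_component(pi / 2, 1), pi / 2)
  expect_equal(seasonal_component(2, sin(2)), 2 * sin(2), tolerance = 1e-12)
  expect_error(seasonal_component(array(0, c(1, 1, 1, 2)), array(0, c(1, 1, 2, 1))),
               "shape mismatch")
  z <- array(rnorm(160, sd = 4), c(2, 2, 5, 8))
  s <- seasonal_component(z, sin(z))
  expect_true(all(abs(s) <= abs(z) + 1e-12))
})

test_that("artifact component is a zero-padded sliding cross-correlation", {
  x <- c(1, 2, 3)
  expect_equal(as.vector(artifact_component(x, matrix(1))), x)
  expect_equal(as.vector(artifact_component(x, matrix(1, 1, 3))), c(3, 6, 5))
  # averaging kernel preserves interior values of a constant signal
  cst <- rep(4, 10)
  a <- as.vector(artifact_component(cst, matrix(1 / 3, 1, 3)))
  expect_equal(a[2:9], rep(4, 8))
  expect_error(artifact_component(x, matrix(1, 1, 2)), "odd")
  expect_error(artifact_component(x, matrix(1, 5, 1)), "exceed")
})

test_that("enk_forward reproduces the scalar worked example and the zero-parameter limit", {
  p <- enk_params(k = 2, l = 1, m = 1)
  d <- enk_forward(c(1, 2), p)
  expect_equal(as.vector(d$Y), c(1, 3 * sin(2) + 2), tolerance = 1e-10)
  # zero affine: first sample collapses to 0, the rest to the artifact term
  p0 <- enk_params(k = 4, l = 1, m = 1)
  p0$w[] <- 0; p0$b[] <- 0
  x <- array(rnorm(2 * 3 * 2 * 4), c(2, 3, 2, 4))
  d0 <- enk_forward(x, p0)
  expect_equal(d0$Y[, , , 1], x[, , , 1] * 0)
  expect_equal(d0$Y[, , , 2:4], x[, , , 2:4])
  expect_equal(d0$A, x)   # identity kernel
})

test_that("enk_forward preserves shape and component bounds on random tensors", {
  set.seed(5)
  x <- array(rnorm(2 * 4 * 8 * 16, sd = 5), c(2, 4, 8, 16))
  p <- enk_params(k = 16, n = 8, l = 3, m = 7, init = "random", seed = 1)
  d <- enk_forward(x, p)
  for (nm in c("Z", "P", "S", "A", "Y")) expect_identical(dim(d[[nm]]), dim(x))
  expect_true(all(abs(d$P) <= 1))
  expect_true(all(abs(d$S) <= abs(d$Z) + 1e-12))
  expect_equal(d$Y[, , , 2:16], (d$P + d$S + d$A)[, , , 2:16])
  expect_equal(d$Y[, , , 1], d$Z[, , , 1])
})

test_that("parameter constructor applies pass-through defaults and validates dimensions", {
  p <- enk_params(k = 16, n = 8, l = 1, m = 7)
  expect_equal(p$w, rep(1, 16))
  expect_equal(p$b, rep(0, 16))
  expect_equal(p$K, matrix(1 / 7, 1, 7))
  expect_equal(enkit:::enk_n_params(p), 2 * 16 + 7)   # 39
  expect_identical(enk_params(k = 16, l = 1, m = 7), enk_params(k = 16, l = 1, m = 7))
  # separate affines double the per-time-step parameters
  ps <- enk_params(k = 16, l = 1, m = 7, shared_affine = FALSE)
  expect_equal(enkit:::enk_n_params(ps), 4 * 16 + 7)
  expect_error(enk_params(k = 0), ">= 1")
  expect_error(enk_params(k = 4, m = 4), "odd")
  expect_error(enk_params(k = 4, n = 2, l = 3), "exceed")
})

test_that("vectorized decomposition matches the scalar loop oracle on 100 random tensors", {
  set.seed(42)
  worst <- 0
  for (r in 1:100) {
    B <- sample(4, 1); M <- sample(4, 1); C <- sample(8, 1); Tn <- sample(16, 1)
    l <- sample(min(3, C), 1)
    m <- sample(c(1, 3, 7), 1)
    x <- array(rnorm(B * M * C * Tn), c(B, M, C, Tn))
    shared <- r %% 2 == 0
    p <- enk_params(k = Tn, n = C, l = l, m = m, shared_affine = shared,
                    init = "random", seed = r)
    Y1 <- enk_forward(x, p)$Y
    Y2 <- if (shared) enk_oracle(x, p$w, p$b, p$K)
          else enk_oracle(x, p$w, p$b, p$K, p$w_s, p$b_s)
    worst <- max(worst, max(abs(Y1 - Y2)))
  }
  expect_lt(worst, 1e-6)
})

test_that("EnK backward matches central finite differences", {
  set.seed(7)
  for (shared in c(TRUE, FALSE)) {
    dm <- c(2, 3, 5, 2)                                  # internal (M, C, T, B)
    x <- array(rnorm(prod(dm)), dm)
    p <- enk_params(k = 5, n = 3, l = 2, m = 3, shared_affine = shared,
                    init = "random", seed = 3)
    wts <- array(rnorm(prod(dm)), dm)                    # fixed loss weights
    loss_of <- function(pp, xx) sum(wts * enkit:::enk_fwd_internal(xx, pp)$Y)
    dec <- enkit:::enk_fwd_internal(x, p)
    g <- enkit:::enk_bwd_internal(x, p, dec, wts)
    modp <- function(field) function(v) { p2 <- p; p2[[field]] <- v; loss_of(p2, x) }
    expect_lt(max(rel_err(num_grad(modp("w"), p$w), g$dw)), 1e-4)
    expect_lt(max(rel_err(num_grad(modp("b"), p$b), g$db)), 1e-4)
    expect_lt(max(rel_err(num_grad(modp("K"), p$K), g$dK)), 1e-4)
    expect_lt(max(rel_err(num_grad(function(v) loss_of(p, array(v, dm)), x),
                          g$dx)), 1e-4)
    if (!shared) {
      expect_lt(max(rel_err(num_grad(modp("w_s"), p$w_s), g$dw_s)), 1e-4)
      expect_lt(max(rel_err(num_grad(modp("b_s"), p$b_s), g$db_s)), 1e-4)
    }
  }
})

test_that("signal tensor coercion fixes the axis order and rejects bad input", {
  expect_identical(dim(as_signal_tensor(1:5)), c(1L, 1L, 1L, 5L))
  expect_identical(dim(as_signal_tensor(matrix(0, 3, 7))), c(1L, 1L, 3L, 7L))
  expect_identical(dim(as_signal_tensor(array(0, c(2, 3, 4)))), c(1L, 2L, 3L, 4L))
  expect_error(as_signal_tensor(c(1, Inf)), "non-finite")
  expect_error(as_signal_tensor("a"), "numeric")
})
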