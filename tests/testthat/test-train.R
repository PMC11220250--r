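test_that("stratified split is exact on divisible cases and obeys the partition law", {
  es <- toy_epochs(n_per_class = 5)   # 10 epochs, 5/5
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(vapply(sp$indices, length, integer(1)),
               c(train = 6L, val = 2L, test = 2L))
  for (part in c("train", "val", "test"))
    expect_equal(as.integer(table(sp[[part]]$labels)),
                 rep(length(sp$indices[[part]]) %/% 2L, 2L))
  all_idx <- sort(unname(unlist(sp$indices)))
  expect_identical(all_idx, 1:10)
  expect_equal(length(unique(unlist(sp$indices))), 10L)
})

test_that("non-divisible class sizes allocate by floor with the remainder to train", {
  es <- toy_epochs(n_per_class = 7)   # 7 per class
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 2)
  # per class: floor(4.2, 1.4, 1.4) = 4/1/1, remainder 1 -> train
  expect_equal(vapply(sp$indices, length, integer(1)),
               c(train = 10L, val = 2L, test = 2L))
  expect_identical(stratified_split(es, c(0.6, 0.2, 0.2), seed = 2)$indices,
                   sp$indices)
  expect_error(stratified_split(toy_epochs(n_per_class = 3), c(0.6, 0.2, 0.2)),
               "class 0")
})

test_that("stratification and determinism hold across random label vectors", {
  set.seed(31)
  for (r in 1:100) {
    n_cls <- sample(2:4, 1)
    per <- sample(5:20, n_cls, replace = TRUE)
    n <- sum(per)
    dat <- array(rnorm(n * 2 * 8), c(n, 2, 8))
    labels <- rep(seq_len(n_cls) - 1L, per)[sample.int(n)]
    es <- epoch_set(dat, labels, 128, c("a", "b"))
    sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = r)
    expect_identical(sort(unname(unlist(sp$indices))), seq_len(n))
    for (k in seq_len(n_cls) - 1L) {
      nk <- sum(labels == k)
      expect_equal(sum(sp$val$labels == k), floor(0.2 * nk))
      expect_equal(sum(sp$test$labels == k), floor(0.2 * nk))
    }
  }
})

test_that("MSE and F1 match hand-computed values on the printed toy cases", {
  expect_equal(mse_score(0L, matrix(c(0.8, 0.2), 1)), 0.04)
  # TP=1, FP=1, FN=0 -> F1 = 2/3
  expect_equal(as.numeric(f1_score(c(1L, 0L), c(1L, 1L))), 2 / 3)
  # weighted multiclass: the support-weighted mean of the per-class scores
  weighted_mean_oracle <- function(per, support) sum(per * support) / sum(support)
  expect_equal(weighted_mean_oracle(c(1, 0.5, 0), c(2, 1, 1)), 0.625)
  # and the implementation reproduces hand-derived per-class + weighted values:
  # class 0: TP=2 -> 1; class 1: TP=1, FP=1 -> 2/3; class 2: FN=1 -> 0
  labels <- c(0L, 0L, 1L, 2L)
  pred <- c(0L, 0L, 1L, 1L)
  f <- f1_score(labels, pred, n_classes = 3L)
  expect_equal(attr(f, "per_class"), c(1, 2 / 3, 0))
  expect_equal(as.numeric(f), weighted_mean_oracle(c(1, 2 / 3, 0), c(2, 1, 1)))
})

test_that("binary F1 matches the closed form on every 2x2 confusion table with counts <= 3", {
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) for (tn in 0:3) {
    if (tp + fp + fn + tn == 0) next
    labels <- c(rep(1L, tp), rep(0L, fp), rep(1L, fn), rep(0L, tn))
    pred <- c(rep(1L, tp), rep(1L, fp), rep(0L, fn), rep(0L, tn))
    expected <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(as.numeric(f1_score(labels, pred, n_classes = 2L)), expected,
                 info = paste(tp, fp, fn, tn))
  }
})

test_that("MSE equals the mean squared one-hot residual over epochs and classes", {
  set.seed(13)
  for (r in 1:20) {
    n <- sample(1:6, 1); k <- sample(2:4, 1)
    p <- matrix(runif(n * k), n); p <- p / rowSums(p)
    y <- sample(seq_len(k) - 1L, n, replace = TRUE)
    acc <- 0
    for (i in 1:n) for (j in 1:k)
      acc <- acc + (as.numeric(y[i] == j - 1L) - p[i, j])^2
    expect_equal(mse_score(y, p), acc / (n * k))
  }
})

test_that("early stopping halts at patience + 1 epochs without improvement and keeps the first epoch", {
  es <- toy_epochs(n_per_class = 6)
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 3)
  net <- build_model(model_spec("eegnet", 3, 32, 2, scale = 0.25), seed = 4)
  # zero learning rate plus frozen batch-norm statistics hold the model
  # constant, so the validation loss never improves after the first epoch
  # and the stopping rule is forced
  for (i in seq_along(net$layers))
    if (net$layers[[i]]$type == "batchnorm") net$layers[[i]]$cfg$momentum <- 0
  cfg <- train_config(max_epochs = 20, patience = 3, learning_rate = 0,
                      batch_size = 4, seed = 5)
  fit <- fit_network(net, sp$train, sp$val, cfg)
  expect_equal(nrow(fit$history), 4L)   # patience + 1
  expect_equal(fit$best_epoch, 1L)
})

test_that("training restores the best-validation weights and is seed-deterministic", {
  es <- toy_epochs(n_per_class = 12)
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 6)
  cfg <- train_config(max_epochs = 15, patience = 5, batch_size = 8, seed = 7)
  net <- build_model(model_spec("eegnet", 3, 32, 2, scale = 0.25), seed = 8)
  fit <- fit_network(net, sp$train, sp$val, cfg)
  # restored weights reproduce the best recorded validation loss exactly
  val_probs <- enkit:::net_eval_probs(fit$net, sp$val)
  expect_equal(enkit:::cross_entropy(t(val_probs), sp$val$labels),
               min(fit$history$val_loss), tolerance = 1e-12)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  # separable toy task: training loss improves over the first epoch
  expect_lt(fit$history$train_loss[fit$best_epoch],
            fit$history$train_loss[1] + 1e-12)
  net2 <- build_model(model_spec("eegnet", 3, 32, 2, scale = 0.25), seed = 8)
  fit2 <- fit_network(net2, sp$train, sp$val, cfg)
  expect_identical(fit$history, fit2$history)
})

test_that("training aborts with diagnostics when the loss turns non-finite", {
  es <- toy_epochs(n_per_class = 5)
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 9)
  net <- build_model(model_spec("eegnet", 3, 32, 2, scale = 0.25), seed = 10)
  net$layers[[1]]$params$W[] <- 1e308   # force overflow
  cfg <- train_config(max_epochs = 3, patience = 2, batch_size = 4, seed = 11)
  expect_error(fit_network(net, sp$train, sp$val, cfg), "epoch 1, batch 1")
})

test_that("evaluation flags classes absent from the test set", {
  es <- toy_epochs(n_per_class = 8)
  sp <- stratified_split(es, c(0.6, 0.2, 0.2), seed = 12)
  net <- build_model(model_spec("eegnet", 3, 32, 3, scale = 0.25), seed = 13)
  expect_warning(r <- evaluate_model(net, sp$test), "class 2 absent")
  expect_equal(r$per_class_f1[3], 0)
  expect_true(r$mse >= 0 && r$f1 >= 0 && r$f1 <= 1)
  expect_error(evaluate_model(net, sp$test[integer(0)]), "empty test set")
})

test_that("paired comparison shares the split and differs only in the EnK flag", {
  es <- toy_epochs(n_per_class = 10)
  spec <- model_spec("eegnet", 3, 32, 2, scale = 0.25)
  cfg <- train_config(max_epochs = 4, patience = 2, batch_size = 8, seed = 14)
  cmp <- compare_enk(spec, es, cfg)
  expect_identical(cmp$split, stratified_split(es, cfg$split, cfg$seed)$indices)
  expect_false(cmp$fit_base$net$spec$enk_enabled)
  expect_true(cmp$fit_enk$net$spec$enk_enabled)
  expect_false(identical(cmp$base$config_hash, cmp$enk$config_hash))
  expect_equal(cmp$delta$f1, cmp$enk$f1 - cmp$base$f1)
  expect_equal(cmp$delta$mse, cmp$enk$mse - cmp$base$mse)
  expect_equal(cmp$base$n_test, cmp$enk$n_test)
})

test_that("configuration bounds mirror the training protocol", {
  expect_error(train_config(batch_size = 32), "\\[2, 16\\]")
  expect_error(train_config(dropout = 0.1), "\\[0.15, 0.75\\]")
  expect_error(train_config(split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(train_config(patience = 200, max_epochs = 200), "patience")
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$patience, 20L)
  expect_equal(cfg$max_epochs, 200L)
  expect_equal(cfg$split, c(0.6, 0.2, 0.2))
})
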