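#' Training configuration
#'
#' The training protocol: Adam (learning rate 0.001) for at most 200 epochs
#' with early stopping once the monitored validation loss has not improved
#' for `patience` (20) consecutive epochs; the weights of the best
#' validation epoch are restored. Data are divided 60/20/20 into
#' train/validation/test by stratified sampling. Batch size must lie in
#' `[2, 16]` and dropout in `[0.15, 0.75]`.
#'
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size, in `[2, 16]`.
#' @param dropout Dropout fraction, in `[0.15, 0.75]`.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs (< `max_epochs`).
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Master seed; split, weight init, batch order and dropout all
#'   derive from it, so paired runs are exactly comparable.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 16L, dropout = 0.25,
                         learning_rate = 0.001, patience = 20L,
                         split = c(0.60, 0.20, 0.20), seed = 1L) {
  if (batch_size < 2L || batch_size > 16L)
    stop("batch_size must lie in [2, 16], got ", batch_size, call. = FALSE)
  if (dropout < 0.15 || dropout > 0.75)
    stop("dropout must lie in [0.15, 0.75], got ", dropout, call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1, got ", paste(split, collapse = "/"), call. = FALSE)
  if (patience >= max_epochs)
    stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 learning_rate = learning_rate, patience = as.integer(patience),
                 split = split, seed = as.integer(seed), monitor = "val_loss"),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Partitions an epoch set preserving per-class proportions to within one
#' epoch: within every class the (seeded) shuffled indices are allocated by
#' `floor(fraction * n_class)` per partition and any remainder goes to the
#' training partition. Partitions are disjoint and exhaustive.
#'
#' @param es An [epoch_set()]; every class needs enough epochs to place at
#'   least one in each partition.
#' @param fractions Length-3 fractions (train, validation, test) summing to 1.
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List with `epoch_set`s `train`, `val`, `test` and the integer
#'   `indices` of each partition in the original set.
#' @export
stratified_split <- function(es, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(es, "epoch_set"))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  set.seed(derive_seed(seed, "split"))
  idx <- list(train = integer(), val = integer(), test = integer())
  for (k in sort(unique(es$labels))) {
    ki <- which(es$labels == k)
    nk <- length(ki)
    alloc <- floor(fractions * nk)
    if (any(alloc == 0 & fractions > 0))
      stop("class ", k, " has only ", nk,
           " epochs: too small to appear in all partitions", call. = FALSE)
    alloc[1] <- alloc[1] + nk - sum(alloc)   # remainder to train
    ki <- ki[sample.int(nk)]
    idx$train <- c(idx$train, ki[seq_len(alloc[1])])
    idx$val <- c(idx$val, ki[alloc[1] + seq_len(alloc[2])])
    idx$test <- c(idx$test, ki[alloc[1] + alloc[2] + seq_len(alloc[3])])
  }
  idx <- lapply(idx, sort)
  list(train = es[idx$train], val = es[idx$val], test = es[idx$test],
       indices = idx)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, flat, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (key in names(flat)) {
    g <- grads[[key]]
    if (is.null(g)) next
    opt$m[[key]] <- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
    opt$v[[key]] <- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g * g
    flat[[key]] <- flat[[key]] -
      lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + opt$eps)
  }
  list(opt = opt, flat = flat)
}

cross_entropy <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(labels + 1L, seq_along(labels))], 1e-12)))
}

# forward pass in inference mode over a whole set, batched
net_eval_probs <- function(net, es, batch = 64L) {
  n <- dim(es$data)[1]
  probs <- matrix(0, n, net$spec$n_classes)
  for (s in seq(1L, n, by = batch)) {
    sel <- s:min(n, s + batch - 1L)
    x <- apply_norm(net, epochs_to_internal(es$data[sel, , , drop = FALSE]))
    probs[sel, ] <- t(softmax_cols(net_forward(net, x, training = FALSE)$logits))
  }
  probs
}

#' Train a network with Adam and early stopping
#'
#' Runs the training protocol of [train_config()]: shuffled mini-batches,
#' softmax cross-entropy loss, Adam updates, per-epoch validation loss, and
#' early stopping with best-weight restoration. Batch-norm running moments
#' follow the weights of the restored epoch. Training aborts with
#' diagnostics if the loss turns non-finite.
#'
#' @param net An [build_model()] network.
#' @param train,val `epoch_set`s for fitting and monitoring.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `enk_fit`: list with the trained `net`,
#'   `history` (data frame: epoch, train_loss, val_loss), `best_epoch`,
#'   `best_val_loss` and `config`.
#' @export
fit_network <- function(net, train, val, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "enk_network"), inherits(cfg, "train_config"))
  if (is.null(net$norm)) net$norm <- fit_norm(train)
  n_tr <- dim(train$data)[1]
  lab_tr <- train$labels
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, epoch = 0L, flat = collect_params(net),
               buffers = lapply(net$layers, `[[`, "buffers"))
  opt <- adam_init(best$flat)
  wait <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    set.seed(derive_seed(cfg$seed, "epoch", ep))
    ord <- sample.int(n_tr)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n_tr, by = cfg$batch_size)) {
      sel <- ord[s:min(n_tr, s + cfg$batch_size - 1L)]
      x <- apply_norm(net, epochs_to_internal(train$data[sel, , , drop = FALSE]))
      y <- lab_tr[sel]
      fwd <- net_forward(net, x, training = TRUE, keep = TRUE)
      net <- fwd$net
      probs <- softmax_cols(fwd$logits)
      loss <- cross_entropy(probs, y)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, ", batch ", nb + 1L,
             " (loss = ", loss, ")", call. = FALSE)
      onehot <- matrix(0, nrow(probs), ncol(probs))
      onehot[cbind(y + 1L, seq_along(y))] <- 1
      dlogits <- (probs - onehot) / length(y)
      bk <- net_backward(net, fwd$xs, fwd$caches, dlogits)
      flat <- collect_params(net)
      gflat <- list()
      for (i in seq_along(bk$grads))
        for (nm in names(bk$grads[[i]]))
          gflat[[paste0(i, ".", nm)]] <- bk$grads[[i]][[nm]]
      st <- adam_step(opt, flat, gflat, cfg$learning_rate)
      opt <- st$opt
      net <- set_params(net, st$flat)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    val_probs <- net_eval_probs(net, val)
    val_loss <- cross_entropy(t(val_probs), val$labels)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss / nb, val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, epoch = ep, flat = collect_params(net),
                   buffers = lapply(net$layers, `[[`, "buffers"))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  net <- set_params(net, best$flat)
  for (i in seq_along(net$layers)) net$layers[[i]]$buffers <- best$buffers[[i]]
  structure(list(net = net, history = history, best_epoch = best$epoch,
                 best_val_loss = best$val, config = cfg),
            class = "enk_fit")
}

#' @export
print.enk_fit <- function(x, ...) {
  cat("<enk_fit> ", x$net$spec$architecture,
      if (x$net$spec$enk_enabled) " + EnK" else "", ": trained ",
      nrow(x$history), " epochs, best epoch ", x$best_epoch,
      " (val loss ", signif(x$best_val_loss, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.enk_fit <- function(object, ...) {
  cat("Training summary\n")
  print(object)
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.enk_fit <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, lwd = 2, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1, lwd = 2,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
predict.enk_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  predict(object$net, newdata, type = match.arg(type), ...)
}

#' @export
coef.enk_fit <- function(object, ...) collect_params(object$net)

#' Evaluate a trained model on a test set
#'
#' Computes the mean squared error between one-hot labels and predicted
#' probabilities and the F1 score (binary: positive class; multiclass:
#' support-weighted). A class absent from the test set is scored 0 in the
#' per-class table and flagged with a warning.
#'
#' @param fit An `enk_fit` (or bare `enk_network`).
#' @param test An [epoch_set()].
#' @return An object of class `eval_report`: `mse`, `f1`, `per_class_f1`,
#'   `n_test`, `config_hash`, `best_epoch`, `warnings`.
#' @export
evaluate_model <- function(fit, test) {
  net <- if (inherits(fit, "enk_fit")) fit$net else fit
  if (dim(test$data)[1] == 0L) stop("empty test set", call. = FALSE)
  probs <- net_eval_probs(net, test)
  pred <- max.col(probs) - 1L
  mse <- mse_score(test$labels, probs)
  f1 <- f1_score(test$labels, pred, n_classes = net$spec$n_classes)
  warns <- character()
  missing_cls <- setdiff(seq_len(net$spec$n_classes) - 1L, unique(test$labels))
  if (length(missing_cls)) {
    warns <- paste0("class ", missing_cls, " absent from test set; per-class F1 set to 0")
    warning(paste(warns, collapse = "; "), call. = FALSE)
  }
  structure(list(mse = mse, f1 = as.numeric(f1),
                 per_class_f1 = as.numeric(attr(f1, "per_class")),
                 n_test = dim(test$data)[1],
                 config_hash = object_hash(list(spec = unclass(net$spec),
                                                cfg = if (inherits(fit, "enk_fit"))
                                                  unclass(fit$config) else NULL)),
                 best_epoch = if (inherits(fit, "enk_fit")) fit$best_epoch else NA_integer_,
                 warnings = warns),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n_test =", x$n_test,
      sprintf(" MSE = %.4f  F1 = %.4f\n", x$mse, x$f1))
  cat("  per-class F1:", paste(signif(x$per_class_f1, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Paired with/without-EnK experiment
#'
#' Trains the identical architecture twice from the same master seed — same
#' stratified split, same initialization stream, same batch orders —
#' differing only in whether the EnK layer is enabled, and evaluates both on
#' the shared test partition.
#'
#' @param spec A [model_spec()]; its `enk_enabled` flag is overridden per arm.
#' @param es An [epoch_set()].
#' @param cfg A [train_config()].
#' @param verbose Forwarded to [fit_network()].
#' @return An object of class `enk_comparison`: `base` and `enk`
#'   `eval_report`s, fitted models, `delta` (list with `mse` and `f1`,
#'   EnK minus base), and the shared `split` indices.
#' @export
compare_enk <- function(spec, es, cfg = train_config(), verbose = FALSE) {
  sp <- stratified_split(es, cfg$split, cfg$seed)
  arms <- list()
  for (arm in c("base", "enk")) {
    s2 <- spec
    s2$enk_enabled <- (arm == "enk")
    s2$dropout_rate <- cfg$dropout
    net <- build_model(s2, seed = derive_seed(cfg$seed, "init"))
    fit <- fit_network(net, sp$train, sp$val, cfg, verbose = verbose)
    arms[[arm]] <- list(fit = fit, report = evaluate_model(fit, sp$test))
  }
  structure(list(base = arms$base$report, enk = arms$enk$report,
                 fit_base = arms$base$fit, fit_enk = arms$enk$fit,
                 delta = list(mse = arms$enk$report$mse - arms$base$report$mse,
                              f1 = arms$enk$report$f1 - arms$base$report$f1),
                 split = sp$indices),
            class = "enk_comparison")
}

#' @export
print.enk_comparison <- function(x, ...) {
  cat("Paired comparison (same seed, split and batch order):\n")
  cat(sprintf("  base: MSE %.4f  F1 %.4f\n", x$base$mse, x$base$f1))
  cat(sprintf("  EnK : MSE %.4f  F1 %.4f\n", x$enk$mse, x$enk$f1))
  cat(sprintf("  delta (EnK - base): MSE %+.4f  F1 %+.4f\n",
              x$delta$mse, x$delta$f1))
  invisible(x)
}
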