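#' Declarative model specification
#'
#' Describes one of the four baseline EEG classification architectures and
#' whether an EnK layer is spliced in directly after the first convolution.
#' The spec fully determines the network topology and parameter count.
#'
#' Canonical configurations follow the architectures' original publications:
#' EEGNet-8,2 (temporal kernel 64, depth multiplier 2, separable kernel 16,
#' pools 4 and 8), ShallowConvNet (40 filters, temporal kernel 25, square /
#' log nonlinearities around a 75/15 average pool), DeepConvNet (four
#' convolutional blocks of 25/50/100/200 filters, kernel 10, max-pool 3) and
#' a recurrent convolutional network with five weight-shared recurrent
#' convolution layers of three iterations each. `scale` multiplies filter
#' counts (topology unchanged) for small-scale experiments.
#'
#' @param architecture One of `"eegnet"`, `"shallowconvnet"`,
#'   `"deepconvnet"`, `"rcnn"`.
#' @param n_channels,n_samples Input epoch geometry.
#' @param n_classes Number of classes (>= 2); the softmax head is sized to it.
#' @param enk_enabled Insert an EnK layer after the first convolution.
#' @param enk_config List with artifact-kernel rows `l`, columns `m` (odd)
#'   and `shared_affine`.
#' @param dropout_rate Dropout fraction in `[0.15, 0.75]`.
#' @param scale Width multiplier (> 0) applied to filter counts.
#' @return An object of class `enk_model_spec`.
#' @export
model_spec <- function(architecture = c("eegnet", "shallowconvnet",
                                        "deepconvnet", "rcnn"),
                       n_channels, n_samples, n_classes = 2L,
                       enk_enabled = FALSE,
                       enk_config = list(l = 1L, m = 7L, shared_affine = TRUE),
                       dropout_rate = 0.25, scale = 1) {
  architecture <- match.arg(architecture)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2, got ", n_classes, call. = FALSE)
  if (dropout_rate < 0.15 || dropout_rate > 0.75)
    stop("dropout_rate must lie in [0.15, 0.75], got ", dropout_rate, call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  enk_config <- utils::modifyList(list(l = 1L, m = 7L, shared_affine = TRUE), enk_config)
  if (enk_config$m %% 2L == 0L)
    stop("enk_config$m must be odd, got ", enk_config$m, call. = FALSE)
  structure(list(architecture = architecture,
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = n_classes,
                 enk_enabled = isTRUE(enk_enabled),
                 enk_config = enk_config,
                 dropout_rate = dropout_rate,
                 scale = scale),
            class = "enk_model_spec")
}

#' @export
print.enk_model_spec <- function(x, ...) {
  cat("Model spec:", x$architecture,
      sprintf("(%d ch x %d samples -> %d classes)", x$n_channels, x$n_samples,
              x$n_classes),
      if (x$enk_enabled) "+ EnK" else "", "\n")
  invisible(x)
}

scaled <- function(n, scale) max(1L, as.integer(round(n * scale)))

# Layer stacks (everything before the dense head). Each returns the layer
# list; the time length after the first convolution is attached for the EnK.
arch_stack <- function(spec) {
  C <- spec$n_channels; Tn <- spec$n_samples; s <- spec$scale
  dr <- spec$dropout_rate
  add_enk <- function(layers, maps, k_time) {
    if (!spec$enk_enabled) return(layers)
    ec <- spec$enk_config
    p <- enk_params(k = k_time, n = C, l = ec$l, m = ec$m,
                    shared_affine = ec$shared_affine)
    c(layers, list(layer_enk("enk", p)))
  }
  if (spec$architecture == "eegnet") {
    F1 <- scaled(8L, s); D <- 2L; F2 <- F1 * D
    kt <- min(64L, max(2L, Tn %/% 2L))
    layers <- list(layer_conv("conv1", 1L, F1, 1L, kt, pad = "same", bias = FALSE))
    layers <- add_enk(layers, F1, Tn)
    layers <- c(layers, list(
      layer_batchnorm("bn1", F1),
      layer_conv("depthwise", F1, F2, C, 1L, pad = "valid", groups = F1, bias = FALSE),
      layer_batchnorm("bn2", F2),
      layer_activation("elu1", "elu"),
      layer_pool("pool1", "avg", 4L),
      layer_dropout("drop1", dr),
      layer_conv("sep_depth", F2, F2, 1L, 16L, pad = "same", groups = F2, bias = FALSE),
      layer_conv("sep_point", F2, F2, 1L, 1L, pad = "valid", bias = FALSE),
      layer_batchnorm("bn3", F2),
      layer_activation("elu2", "elu"),
      layer_pool("pool2", "avg", 8L),
      layer_dropout("drop2", dr)))
    return(layers)
  }
  if (spec$architecture == "shallowconvnet") {
    Fc <- scaled(40L, s)
    layers <- list(layer_conv("conv_time", 1L, Fc, 1L, 25L, pad = "valid", bias = FALSE))
    layers <- add_enk(layers, Fc, Tn - 24L)
    layers <- c(layers, list(
      layer_conv("conv_spat", Fc, Fc, C, 1L, pad = "valid", bias = FALSE),
      layer_batchnorm("bn1", Fc),
      layer_activation("square", "square"),
      layer_pool("pool1", "avg", 75L, 15L),
      layer_activation("log", "safelog"),
      layer_dropout("drop1", dr)))
    return(layers)
  }
  if (spec$architecture == "deepconvnet") {
    Fs <- vapply(c(25L, 50L, 100L, 200L), scaled, integer(1), scale = s)
    layers <- list(layer_conv("conv_time", 1L, Fs[1], 1L, 10L, pad = "valid", bias = FALSE))
    layers <- add_enk(layers, Fs[1], Tn - 9L)
    layers <- c(layers, list(
      layer_conv("conv_spat", Fs[1], Fs[1], C, 1L, pad = "valid", bias = FALSE),
      layer_batchnorm("bn1", Fs[1]),
      layer_activation("elu1", "elu"),
      layer_pool("pool1", "max", 3L),
      layer_dropout("drop1", dr)))
    for (i in 2:4) {
      layers <- c(layers, list(
        layer_conv(paste0("conv", i), Fs[i - 1], Fs[i], 1L, 10L, pad = "valid", bias = FALSE),
        layer_batchnorm(paste0("bn", i), Fs[i]),
        layer_activation(paste0("elu", i), "elu"),
        layer_pool(paste0("pool", i), "max", 3L),
        layer_dropout(paste0("drop", i), dr)))
    }
    return(layers)
  }
  # rcnn
  Fc <- scaled(32L, s)
  layers <- list(layer_conv("conv0", 1L, Fc, 1L, 5L, pad = "same", bias = FALSE))
  layers <- add_enk(layers, Fc, Tn)
  layers <- c(layers, list(
    layer_batchnorm("bn0", Fc),
    layer_activation("elu0", "elu"),
    layer_conv("conv_spat", Fc, Fc, C, 1L, pad = "valid", bias = FALSE),
    layer_batchnorm("bn_spat", Fc),
    layer_activation("elu_spat", "elu")))
  for (i in 1:5) {
    layers <- c(layers, list(layer_rcl(paste0("rcl", i), Fc)))
    if (i %in% c(2L, 4L))
      layers <- c(layers, list(layer_pool(paste0("pool", i), "max", 2L)))
  }
  layers <- c(layers, list(layer_dropout("drop_out", dr)))
  layers
}

# run a zero tensor through the stack to size the dense head
stack_out_shape <- function(layers, C, Tn) {
  x <- array(0, c(1L, C, Tn, 1L))
  for (ly in layers) x <- layer_forward(ly, x, training = FALSE)$out
  dim(x)[1:3]
}

#' Build a model from its specification
#'
#' Instantiates the architecture named in the spec with freshly initialized
#' weights, splicing an EnK layer immediately after the first convolution
#' when `enk_enabled` is set, and a softmax classification head sized to
#' `n_classes`. Weight initialization consumes the R random stream; call
#' `set.seed()` (or pass `seed`) for reproducible builds.
#'
#' @param spec An [model_spec()] object.
#' @param seed Optional integer seed for the weight initialization.
#' @return An object of class `enk_network`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "enk_model_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  layers <- arch_stack(spec)
  shp <- tryCatch(stack_out_shape(layers, spec$n_channels, spec$n_samples),
                  error = function(e) e)
  if (inherits(shp, "error")) {
    min_T <- NA_integer_
    for (Tt in seq(spec$n_samples + 1L, 4096L)) {
      s2 <- spec; s2$n_samples <- Tt
      ok <- tryCatch({
        stack_out_shape(arch_stack(s2), spec$n_channels, Tt); TRUE
      }, error = function(e) FALSE)
      if (ok) { min_T <- Tt; break }
    }
    stop("input too short for ", spec$architecture, ": n_samples=",
         spec$n_samples, " does not survive the stacked pooling; minimal ",
         "n_samples is ", min_T, call. = FALSE)
  }
  n_feat <- prod(shp)
  layers <- c(layers, list(layer_dense("dense", n_feat, spec$n_classes)))
  structure(list(spec = spec, layers = layers,
                 input_shape = c(1L, spec$n_channels, spec$n_samples),
                 norm = NULL),
            class = "enk_network")
}

# ---- forward / backward over a whole network ------------------------------

softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max), `-`)
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# x: internal tensor (1, C, T, B). Returns logits (n_classes x B) plus the
# per-layer inputs and caches needed for backprop and Grad-CAM.
net_forward <- function(net, x, training = FALSE, keep = FALSE) {
  n <- length(net$layers)
  xs <- if (keep) vector("list", n) else NULL
  caches <- if (keep) vector("list", n) else NULL
  for (i in seq_len(n)) {
    if (keep) xs[[i]] <- x
    st <- layer_forward(net$layers[[i]], x, training = training)
    if (keep) caches[[i]] <- st$cache
    net$layers[[i]] <- st$layer
    x <- st$out
  }
  list(logits = x, xs = xs, caches = caches, net = net)
}

# dlogits: gradient at the logits. Returns per-layer grads and input grad.
net_backward <- function(net, xs, caches, dlogits, upto = 0L) {
  n <- length(net$layers)
  grads <- vector("list", n)
  d <- dlogits
  for (i in seq(n, upto + 1L)) {
    bk <- layer_backward(net$layers[[i]], xs[[i]], caches[[i]], d)
    grads[[i]] <- bk$grads
    d <- bk$dx
  }
  list(grads = grads, dx = d)
}

collect_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    ps <- net$layers[[i]]$params
    for (nm in names(ps)) {
      if (is.null(ps[[nm]])) next
      out[[paste0(i, ".", nm)]] <- ps[[nm]]
    }
  }
  out
}

set_params <- function(net, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    net$layers[[i]]$params[[parts[2]]] <- flat[[key]]
  }
  net
}

count_params <- function(net) {
  sum(vapply(collect_params(net), length, numeric(1)))
}

# ---- S3 surface -----------------------------------------------------------

#' @export
print.enk_network <- function(x, ...) {
  cat("<enk_network> ", x$spec$architecture,
      if (x$spec$enk_enabled) " + EnK" else "",
      ": ", x$spec$n_channels, " ch x ", x$spec$n_samples, " samples -> ",
      x$spec$n_classes, " classes, ", format(count_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

#' Layer table of a built network
#'
#' @param object An `enk_network`.
#' @param ... Unused.
#' @return A data frame with one row per layer: name, type, output shape
#'   (for a single input epoch) and trainable parameter count; total equals
#'   the sum of the rows.
#' @export
summary.enk_network <- function(object, ...) {
  x <- array(0, c(1L, object$spec$n_channels, object$spec$n_samples, 1L))
  rows <- lapply(seq_along(object$layers), function(i) {
    ly <- object$layers[[i]]
    st <- layer_forward(ly, x, training = FALSE)
    x <<- st$out
    np <- sum(vapply(ly$params, function(p) if (is.null(p)) 0 else length(p),
                     numeric(1)))
    d <- dim(st$out) %||% c(length(st$out), 1L)
    data.frame(name = ly$name, type = ly$type,
               output_shape = paste(utils::head(d, -1L), collapse = "x"),
               n_params = np, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$n_params)
  class(out) <- c("enk_network_summary", class(out))
  out
}

#' @export
print.enk_network_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("total parameters:", attr(x, "total_params"), "\n")
  invisible(x)
}

#' Class probabilities from a network
#'
#' @param object An `enk_network`.
#' @param newdata An `epoch_set` or a numeric array of epochs
#'   `(epochs, channels, samples)`.
#' @param type `"prob"` for a matrix of class probabilities (rows sum to 1)
#'   or `"class"` for integer labels.
#' @param ... Unused.
#' @export
predict.enk_network <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- apply_norm(object, epochs_to_internal(newdata))
  p <- t(softmax_cols(net_forward(object, x, training = FALSE)$logits))
  colnames(p) <- paste0("class", seq_len(ncol(p)) - 1L)
  if (type == "class") return(max.col(p) - 1L)
  p
}

#' @export
coef.enk_network <- function(object, ...) collect_params(object)

# epochs (E, C, T) or epoch_set -> internal (1, C, T, E)
epochs_to_internal <- function(es) {
  a <- if (inherits(es, "epoch_set")) es$data else es
  if (length(dim(a)) != 3L) stop("expected epochs as (epochs, channels, samples)", call. = FALSE)
  aperm(array(a, c(dim(a), 1L)), c(4L, 2L, 3L, 1L))
}

# per-channel standardization fitted on the training split (protocol step);
# x is an internal (1, C, T, B) tensor
apply_norm <- function(net, x) {
  if (is.null(net$norm)) return(x)
  sweep(sweep(x, 2L, net$norm$mean, `-`), 2L, net$norm$sd, `/`)
}

fit_norm <- function(es) {
  m <- apply(es$data, 2L, mean)
  s <- apply(es$data, 2L, stats::sd)
  s[!is.finite(s) | s < 1e-8] <- 1
  list(mean = m, sd = s)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `spec.json` (the versioned model
#' specification) and `weights.rds` (all trainable arrays plus batch-norm
#' running moments). The round trip is bit-exact on weights.
#'
#' @param net An `enk_network`.
#' @param dir Checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the rebuilt `enk_network`.
#' @export
save_checkpoint <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- unclass(net$spec)
  spec$checkpoint_version <- 1L
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  buffers <- lapply(net$layers, `[[`, "buffers")
  names(buffers) <- vapply(net$layers, `[[`, "", "name")
  saveRDS(list(params = collect_params(net), buffers = buffers,
               norm = net$norm),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- model_spec(architecture = sj$architecture, n_channels = sj$n_channels,
                     n_samples = sj$n_samples, n_classes = sj$n_classes,
                     enk_enabled = sj$enk_enabled,
                     enk_config = as.list(sj$enk_config),
                     dropout_rate = sj$dropout_rate, scale = sj$scale)
  net <- build_model(spec, seed = 0L)
  wt <- readRDS(file.path(dir, "weights.rds"))
  net <- set_params(net, wt$params)
  for (i in seq_along(net$layers)) {
    nm <- net$layers[[i]]$name
    if (!is.null(wt$buffers[[nm]]) && length(wt$buffers[[nm]]))
      net$layers[[i]]$buffers <- wt$buffers[[nm]]
  }
  net$norm <- wt$norm
  net
}
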