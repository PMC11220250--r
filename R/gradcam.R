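#' Grad-CAM map for one epoch
#'
#' Gradient-weighted class activation mapping over a chosen layer of the
#' network, adapted to multichannel time series: the class score (logit) is
#' backpropagated to the target layer's output, each feature map receives a
#' weight equal to the spatial mean of its gradient, and the heat map is the
#' rectified weighted sum of the feature maps, max-normalized to `[0, 1]`
#' (identically-zero maps stay zero) and linearly resampled along time to
#' the input's sample count so it can be overlaid on the raw signal.
#'
#' By default the map targets the EnK layer's output when the network has
#' one, else the first convolution's output.
#'
#' @param fit An `enk_fit` or `enk_network`.
#' @param epoch One epoch: a channels x samples matrix (or an `epoch_set`
#'   with `epoch_index`).
#' @param target_class Class index (0-based) whose evidence is mapped.
#' @param target_layer Layer name (see `summary()` of the network); default
#'   `"enk"` when present, else the first convolution.
#' @param epoch_index Epoch to use when `epoch` is an `epoch_set`.
#' @return An object of class `gradcam_map`: `heat` (rows x input samples,
#'   values in `[0, 1]`), `heat_raw` (before time resampling),
#'   `target_class`, `target_layer`, `input_ref`, `n_samples`.
#' @export
gradcam <- function(fit, epoch, target_class, target_layer = NULL,
                    epoch_index = 1L) {
  net <- if (inherits(fit, "enk_fit")) fit$net else fit
  if (inherits(epoch, "epoch_set")) {
    input_ref <- paste0("epoch_", epoch_index)
    epoch <- epoch$data[epoch_index, , ]
  } else input_ref <- "epoch"
  epoch <- as.matrix(epoch)
  nms <- vapply(net$layers, `[[`, "", "name")
  if (is.null(target_layer))
    target_layer <- if ("enk" %in% nms) "enk" else nms[match("conv", vapply(net$layers, `[[`, "", "type"))]
  ti <- match(target_layer, nms)
  if (is.na(ti)) stop("unknown layer '", target_layer, "'; layers: ",
                      paste(nms, collapse = ", "), call. = FALSE)
  if (target_class < 0L || target_class >= net$spec$n_classes)
    stop("target_class ", target_class, " out of range [0, ",
         net$spec$n_classes - 1L, "]", call. = FALSE)
  x <- apply_norm(net, array(epoch, c(1L, dim(epoch), 1L)))  # (1, C, T, 1)
  fwd <- net_forward(net, x, training = FALSE, keep = TRUE)
  n <- length(net$layers)
  act <- if (ti < n) fwd$xs[[ti + 1L]] else fwd$logits
  dlogits <- matrix(0, net$spec$n_classes, 1L)
  dlogits[target_class + 1L, 1L] <- 1
  grad <- net_backward(fwd$net, fwd$xs, fwd$caches, dlogits, upto = ti)$dx
  M <- dim(act)[1]
  alpha <- rowMeans(matrix(grad, nrow = M))
  wsum <- apply(array(alpha * array(act, dim(act)), dim(act)), c(2L, 3L), sum)
  heat_raw <- pmax(wsum, 0)
  if (max(heat_raw) > 0) heat_raw <- heat_raw / max(heat_raw)
  Tin <- ncol(epoch)
  Tmap <- ncol(heat_raw)
  heat <- if (Tmap == Tin) heat_raw else
    t(apply(heat_raw, 1L, function(r)
      stats::approx(seq(0, 1, length.out = Tmap), r,
                    xout = seq(0, 1, length.out = Tin))$y))
  structure(list(heat = heat, heat_raw = heat_raw,
                 target_class = as.integer(target_class),
                 target_layer = target_layer, input_ref = input_ref,
                 n_samples = Tin),
            class = "gradcam_map")
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat("<gradcam_map> layer '", x$target_layer, "', class ", x$target_class,
      ", ", nrow(x$heat), " x ", ncol(x$heat), " (max ",
      signif(max(x$heat), 3), ")\n", sep = "")
  invisible(x)
}

#' Difference of two Grad-CAM maps
#'
#' Elementwise `a - b` of the (normalized) heat maps; the result lies in
#' `[-1, 1]` and is deliberately not renormalized.
#'
#' @param a,b `gradcam_map`s of the same shape computed on the same input.
#' @return A `gradcam_map` whose `heat` is the signed difference.
#' @export
diff_map <- function(a, b) {
  stopifnot(inherits(a, "gradcam_map"), inherits(b, "gradcam_map"))
  if (!identical(dim(a$heat), dim(b$heat)))
    stop("heat map shape mismatch: ", paste(dim(a$heat), collapse = "x"),
         " vs ", paste(dim(b$heat), collapse = "x"), call. = FALSE)
  if (!identical(a$input_ref, b$input_ref))
    stop("maps computed on different inputs: '", a$input_ref, "' vs '",
         b$input_ref, "'", call. = FALSE)
  structure(list(heat = a$heat - b$heat, heat_raw = a$heat_raw - b$heat_raw,
                 target_class = a$target_class,
                 target_layer = paste(a$target_layer, "-", b$target_layer),
                 input_ref = a$input_ref, n_samples = a$n_samples),
            class = "gradcam_map")
}

#' Heat-mass fraction inside a time window
#'
#' The fraction of the total Grad-CAM heat that falls into a sample window —
#' used to quantify how time-localized the class evidence is (compare it to
#' the window's share of the epoch duration).
#'
#' @param map A `gradcam_map`.
#' @param window Integer sample indices (1-based) of the window.
#' @return A number in `[0, 1]` (0 if the map is identically zero).
#' @export
heat_mass_fraction <- function(map, window) {
  stopifnot(inherits(map, "gradcam_map"))
  tot <- sum(map$heat)
  if (tot <= 0) return(0)
  sum(map$heat[, window]) / tot
}

#' Render a Grad-CAM overlay figure
#'
#' Writes a PNG with the heat map as background (time on the x axis,
#' channels stacked on the y axis) and the raw per-channel signal drawn as
#' line graphs in front. Rendering is deterministic for fixed inputs.
#'
#' @param map A `gradcam_map`.
#' @param epoch The raw epoch (channels x samples matrix) the map was
#'   computed on.
#' @param path Output PNG path.
#' @param sampling_rate Optional Hz for a time axis in ms.
#' @return `path`, invisibly.
#' @export
overlay <- function(map, epoch, path, sampling_rate = NULL) {
  stopifnot(inherits(map, "gradcam_map"))
  epoch <- as.matrix(epoch)
  if (ncol(epoch) != ncol(map$heat))
    stop("epoch and map are not time-aligned: ", ncol(epoch), " vs ",
         ncol(map$heat), " samples", call. = FALSE)
  nC <- nrow(epoch); Tn <- ncol(epoch)
  xs <- if (is.null(sampling_rate)) seq_len(Tn) else
    (seq_len(Tn) - 1L) / sampling_rate * 1000
  ok <- tryCatch({
    grDevices::png(path, width = 900, height = 120 + 60 * nC)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot open '", path, "' for writing", call. = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::colorRampPalette(c("white", "gold", "orangered", "darkred"))(64)
  rows <- nrow(map$heat)
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(xs, seq_len(rows), t(map$heat), zlim = c(0, max(1, max(map$heat))),
                  col = pal, xlab = if (is.null(sampling_rate)) "sample" else "time (ms)",
                  ylab = "channel", main = paste0("Grad-CAM: ", map$target_layer,
                                                  ", class ", map$target_class))
  scale <- max(abs(epoch))
  if (scale == 0) scale <- 1
  for (ch in seq_len(nC))
    graphics::lines(xs, ch + 0.4 * epoch[ch, ] / scale, col = "grey20", lwd = 1)
  invisible(path)
}
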