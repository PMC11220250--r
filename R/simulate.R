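#' Synthetic EEG epoch specification
#'
#' Describes a seeded generator for labeled EEG-like epochs. Each epoch is
#' the sum of independent components: 1/f (colored) background noise, a
#' class-conditional event-related potential (Gaussian temporal profile at a
#' jittered latency on a target channel subset), a Hann-windowed band-limited
#' oscillation burst, large slow blink transients on frontal channels, and a
#' mains-frequency line-noise sinusoid. Class labels depend only on
#' time-dependent features, so the data exercise a time-encoding layer.
#'
#' @param n_epochs_per_class Epochs generated per class (balanced by
#'   construction).
#' @param n_channels,n_samples,sampling_rate Epoch geometry; `sampling_rate`
#'   in Hz.
#' @param n_classes Number of classes (default 2).
#' @param background List: `exponent` (spectral slope of the 1/f noise,
#'   power ~ f^-exponent) and `amplitude` (standard deviation, arbitrary
#'   units ~ microvolts).
#' @param erp List: `latency_ms`, `width_ms` (Gaussian sigma), `amplitude`,
#'   `sign` (+1/-1), `jitter_ms` (latency standard deviation across epochs),
#'   `channels` (integer indices receiving the deflection).
#' @param oscillation List: `freq_hz`, `amplitude`, `burst_ms` (Hann window
#'   length), `onset_ms`.
#' @param artifacts List: `blink_rate` (expected blinks per epoch),
#'   `blink_amplitude`, `line_freq_hz`, `line_amplitude`.
#' @param class_effect Which component carries the class difference:
#'   `"erp"` (ERP amplitude scales with class index), `"oscillation"`
#'   (burst amplitude scales with class index), or `"erp_channels"` (each
#'   class projects the ERP onto a different channel group).
#' @param channel_names Character vector of length `n_channels`.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_epochs_per_class = 200L,
                       n_channels = 8L, n_samples = 128L, sampling_rate = 128,
                       n_classes = 2L,
                       background = list(exponent = 1, amplitude = 10),
                       erp = list(latency_ms = 300, width_ms = 45,
                                  amplitude = 8, sign = 1, jitter_ms = 20,
                                  channels = NULL),
                       oscillation = list(freq_hz = 10, amplitude = 0,
                                          burst_ms = 400, onset_ms = 250),
                       artifacts = list(blink_rate = 0.1, blink_amplitude = 40,
                                        line_freq_hz = 50, line_amplitude = 1),
                       class_effect = "erp",
                       channel_names = NULL,
                       seed = 1L) {
  background <- utils::modifyList(list(exponent = 1, amplitude = 10), background)
  erp <- utils::modifyList(list(latency_ms = 300, width_ms = 45, amplitude = 8,
                                sign = 1, jitter_ms = 20, channels = NULL), erp)
  oscillation <- utils::modifyList(list(freq_hz = 10, amplitude = 0,
                                        burst_ms = 400, onset_ms = 250), oscillation)
  artifacts <- utils::modifyList(list(blink_rate = 0.1, blink_amplitude = 40,
                                      line_freq_hz = 50, line_amplitude = 1), artifacts)
  if (is.null(erp$channels)) erp$channels <- seq_len(min(4L, n_channels))
  if (is.null(channel_names))
    channel_names <- default_channel_names(n_channels)
  sp <- structure(list(
    n_epochs_per_class = as.integer(n_epochs_per_class),
    n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
    sampling_rate = sampling_rate, n_classes = as.integer(n_classes),
    background = background, erp = erp, oscillation = oscillation,
    artifacts = artifacts, class_effect = class_effect,
    channel_names = channel_names, seed = as.integer(seed)),
    class = "synth_spec")
  validate_synth_spec(sp)
  sp
}

default_channel_names <- function(n) {
  base <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "Pz", "P3", "P4", "Oz",
            "O1", "O2", "T7", "T8", "FCz", "CPz")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("E", seq_len(n - length(base))))
}

validate_synth_spec <- function(sp) {
  errs <- character()
  ms_per_epoch <- sp$n_samples / sp$sampling_rate * 1000
  if (sp$erp$latency_ms + 3 * sp$erp$width_ms > ms_per_epoch)
    errs <- c(errs, sprintf("erp latency %g + 3*width %g ms exceeds epoch length %g ms",
                            sp$erp$latency_ms, sp$erp$width_ms, ms_per_epoch))
  if (sp$oscillation$freq_hz >= sp$sampling_rate / 2)
    errs <- c(errs, sprintf("oscillation frequency %g Hz is not below Nyquist %g Hz",
                            sp$oscillation$freq_hz, sp$sampling_rate / 2))
  if (sp$artifacts$blink_rate < 0 || sp$artifacts$blink_amplitude < 0 ||
      sp$artifacts$line_amplitude < 0)
    errs <- c(errs, "artifact rates and amplitudes must be >= 0")
  if (sp$n_epochs_per_class < 2L)
    errs <- c(errs, "need at least 2 epochs per class")
  if (any(sp$erp$channels > sp$n_channels))
    errs <- c(errs, "erp channel index exceeds n_channels")
  if (length(sp$channel_names) != sp$n_channels)
    errs <- c(errs, "channel_names length must equal n_channels")
  if (length(errs)) stop("invalid synthetic spec:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(sp)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic EEG spec:", x$n_classes, "classes x", x$n_epochs_per_class,
      "epochs,", x$n_channels, "ch x", x$n_samples, "samples @",
      x$sampling_rate, "Hz\n")
  cat("  class effect:", x$class_effect, "| ERP", x$erp$amplitude * x$erp$sign,
      "au @", x$erp$latency_ms, "ms | 1/f exponent", x$background$exponent, "\n")
  invisible(x)
}

#' Named generator presets
#'
#' `p300_like`: rare-target oddball analog — positive parietal deflection at
#' 300 ms, present on the target class only. `conflict_like`: cognitive
#' conflict analog — frontal negativity at 200 ms. `mi_like`: motor-imagery
#' analog — class-dependent alpha-band (10 Hz) burst amplitude.
#' `mrcp_like`: movement-related cortical potential analog — slow (< 3 Hz)
#' negative ramp over 4 classes projected onto different channel groups.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [synth_spec()] fields (applied on top of
#'   the preset values).
#' @return A `synth_spec`.
#' @export
synth_preset <- function(name = c("p300_like", "conflict_like", "mi_like",
                                  "mrcp_like"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    p300_like = list(
      erp = list(latency_ms = 300, width_ms = 45, amplitude = 8, sign = 1,
                 jitter_ms = 20, channels = 4:8),   # centro-parietal subset
      class_effect = "erp"),
    conflict_like = list(
      erp = list(latency_ms = 200, width_ms = 30, amplitude = 8, sign = -1,
                 jitter_ms = 15, channels = 1:3),
      class_effect = "erp"),
    mi_like = list(
      erp = list(amplitude = 0, latency_ms = 300, width_ms = 40),
      oscillation = list(freq_hz = 10, amplitude = 6, burst_ms = 500,
                         onset_ms = 200),
      n_samples = 256L,
      class_effect = "oscillation"),
    mrcp_like = list(
      n_classes = 4L,
      n_samples = 256L,
      erp = list(latency_ms = 1500, width_ms = 150, amplitude = 10, sign = -1,
                 jitter_ms = 40, channels = 4:6),
      class_effect = "erp_channels"))
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

# 1/f colored noise via spectral shaping, one trace per call column.
# Returns an n x m matrix of traces with sd ~ 1 (normalized per trace).
colored_noise <- function(n, m, exponent) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  shape <- f^(-exponent / 2)
  re <- matrix(stats::rnorm(nf * m), nf, m) * shape
  im <- matrix(stats::rnorm(nf * m), nf, m) * shape
  spec <- matrix(0 + 0i, n, m)
  spec[2:(nf + 1L), ] <- complex(real = re, imaginary = im)
  idx <- n - (1:(nf - 1L)) + 1L
  spec[idx, ] <- Conj(spec[2:nf, ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2L, sds, `/`)
}

# class multiplier for the graded component: class 0 -> 0, top class -> 1
class_gain <- function(cls, n_classes) {
  if (n_classes == 2L) as.numeric(cls) else cls / (n_classes - 1)
}

#' Generate a synthetic epoch set
#'
#' Draws the epochs described by a [synth_spec()]: balanced classes, bit
#' reproducible for a fixed spec (including its seed). Components are
#' additive, so zeroing all amplitudes but one isolates that component.
#'
#' @param spec A `synth_spec`.
#' @return An object of class `epoch_set`: list with `data`
#'   `(epochs, channels, samples)`, integer `labels` (0-based), `sampling_rate`,
#'   `channel_names`, `class_names` and `provenance` (the generating spec).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_synth_spec(spec)
  set.seed(spec$seed)
  n_ep <- spec$n_epochs_per_class * spec$n_classes
  C <- spec$n_channels; Tn <- spec$n_samples; sr <- spec$sampling_rate
  tt <- (seq_len(Tn) - 1L) / sr                     # seconds
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_epochs_per_class)
  data <- array(0, c(n_ep, C, Tn))

  bg <- spec$background
  if (bg$amplitude > 0) {
    noise <- colored_noise(Tn, n_ep * C, bg$exponent) * bg$amplitude
    data <- data + aperm(array(noise, c(Tn, C, n_ep)), c(3L, 2L, 1L))
  }

  erp <- spec$erp
  osc <- spec$oscillation
  art <- spec$artifacts
  frontal <- seq_len(max(1L, min(2L, C)))

  for (e in seq_len(n_ep)) {
    cls <- labels[e]
    g <- class_gain(cls, spec$n_classes)
    # ERP deflection
    amp <- erp$amplitude * erp$sign
    chans <- erp$channels
    if (spec$class_effect == "erp") {
      amp <- amp * g
    } else if (spec$class_effect == "erp_channels") {
      grp <- (cls %% spec$n_classes)
      w <- max(1L, C %/% spec$n_classes)
      chans <- (grp * w + 1L):min(C, grp * w + w)
    }
    if (abs(amp) > 0) {
      lat <- (erp$latency_ms + stats::rnorm(1L, 0, erp$jitter_ms)) / 1000
      prof <- amp * exp(-(tt - lat)^2 / (2 * (erp$width_ms / 1000)^2))
      data[e, chans, ] <- data[e, chans, ] +
        matrix(prof, length(chans), Tn, byrow = TRUE)
    }
    # oscillation burst, Hann envelope
    oamp <- osc$amplitude
    if (spec$class_effect == "oscillation") oamp <- oamp * (0.35 + 0.65 * g)
    if (oamp > 0) {
      L <- max(4L, round(osc$burst_ms / 1000 * sr))
      on <- round(osc$onset_ms / 1000 * sr)
      idx <- (on + 1L):min(Tn, on + L)
      hann <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (L + 1L)))
      phase <- stats::runif(1L, 0, 2 * pi)
      burst <- oamp * hann * sin(2 * pi * osc$freq_hz * tt[idx] + phase)
      data[e, , idx] <- data[e, , idx] +
        matrix(burst, C, length(idx), byrow = TRUE)
    }
    # blink transients: slow large positive lobes on frontal channels
    if (art$blink_rate > 0 && art$blink_amplitude > 0) {
      nb <- stats::rpois(1L, art$blink_rate)
      if (nb > 0) for (bk in seq_len(nb)) {
        c0 <- stats::runif(1L, 0.05, 0.95) * Tn / sr
        prof <- art$blink_amplitude * exp(-(tt - c0)^2 / (2 * 0.08^2))
        data[e, frontal, ] <- data[e, frontal, ] +
          matrix(prof, length(frontal), Tn, byrow = TRUE)
      }
    }
    # line noise
    if (art$line_amplitude > 0 && art$line_freq_hz < sr / 2) {
      phase <- stats::runif(1L, 0, 2 * pi)
      data[e, , ] <- data[e, , ] +
        matrix(art$line_amplitude * sin(2 * pi * art$line_freq_hz * tt + phase),
               C, Tn, byrow = TRUE)
    }
  }

  epoch_set(data = data, labels = labels, sampling_rate = sr,
            channel_names = spec$channel_names,
            class_names = paste0("class", seq_len(spec$n_classes) - 1L),
            provenance = unclass(spec))
}

#' Labeled epoch container
#'
#' @param data Numeric array `(epochs, channels, samples)`, finite.
#' @param labels Integer class label per epoch (0-based); every class must
#'   appear at least twice so the set is stratifiable.
#' @param sampling_rate Hz.
#' @param channel_names Character vector, one per channel.
#' @param class_names Optional class names.
#' @param provenance Generating spec or source description (list).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate, channel_names,
                      class_names = NULL, provenance = list()) {
  if (length(dim(data)) != 3L) stop("data must be (epochs, channels, samples)", call. = FALSE)
  if (!all(is.finite(data))) stop("epoch data contains non-finite values", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1])
    stop("labels length ", length(labels), " != epoch count ", dim(data)[1], call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class must appear at least twice; counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "), call. = FALSE)
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must equal channel count", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class", sort(unique(labels)))
  new_epoch_set(data, labels, sampling_rate, channel_names, class_names,
                provenance)
}

# unchecked constructor: partitions of a stratified split may legitimately
# hold a single epoch of a class, so the >= 2 rule applies only to full sets
new_epoch_set <- function(data, labels, sampling_rate, channel_names,
                          class_names, provenance) {
  structure(list(data = data, labels = as.integer(labels),
                 sampling_rate = sampling_rate,
                 channel_names = channel_names, class_names = class_names,
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  tab <- table(x$labels)
  cat("  classes:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.epoch_set <- function(x, channel = 1L, ...) {
  tt <- (seq_len(dim(x$data)[3]) - 1L) / x$sampling_rate * 1000
  cls <- sort(unique(x$labels))
  means <- vapply(cls, function(k) colMeans(x$data[x$labels == k, channel, , drop = FALSE][, 1L, ]),
                  numeric(length(tt)))
  graphics::matplot(tt, means, type = "l", lty = 1, lwd = 2,
                    xlab = "time (ms)", ylab = "amplitude (au)",
                    main = paste0("class-average, channel ", x$channel_names[channel]), ...)
  graphics::legend("topright", legend = paste0("class ", cls), col = seq_along(cls),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Subset an epoch set by epoch index
#' @param x An `epoch_set`.
#' @param i Integer epoch indices.
#' @param ... Unused.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  new_epoch_set(data = x$data[i, , , drop = FALSE], labels = x$labels[i],
                sampling_rate = x$sampling_rate,
                channel_names = x$channel_names,
                class_names = x$class_names, provenance = x$provenance)
}
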