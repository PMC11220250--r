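`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce numeric input to a 4-axis signal tensor
#'
#' Signal tensors follow the axis order (batch, feature maps, channels, time
#' samples), with time as the last axis. Vectors are treated as a single
#' time series, matrices as one channels-by-time epoch.
#'
#' @param x Numeric vector (time series), matrix (channels x time), 3-d array
#'   (maps x channels x time), or 4-d array already in tensor order.
#' @return A 4-d numeric array `(batch, maps, channels, time)`.
#' @export
as_signal_tensor <- function(x) {
  if (!is.numeric(x)) stop("signal tensor must be numeric", call. = FALSE)
  if (!all(is.finite(x))) stop("signal tensor contains non-finite values", call. = FALSE)
  d <- dim(x)
  if (is.null(d)) {
    array(x, c(1L, 1L, 1L, length(x)))
  } else if (length(d) == 2L) {
    array(x, c(1L, 1L, d[1], d[2]))
  } else if (length(d) == 3L) {
    array(x, c(1L, d))
  } else if (length(d) == 4L) {
    x
  } else {
    stop("signal tensor must have at most 4 axes, got ", length(d), call. = FALSE)
  }
}

# (batch, maps, channels, time) -> internal (maps, channels, time, batch)
to_internal <- function(x) aperm(x, c(2L, 3L, 4L, 1L))
from_internal <- function(x) aperm(x, c(4L, 1L, 2L, 3L))

# Small deterministic seed derivation so paired runs can share sub-streams
# without consuming a common RNG state. Kept below 2^31.
derive_seed <- function(seed, tag, i = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + i * 7919) %% 2147483629)
}

# md5 of an R object via its serialized JSON (no digest package dependency)
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
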