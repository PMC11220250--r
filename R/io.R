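# Epoch container: one HDF5 file (/data, /labels) plus a JSON sidecar with
# sampling metadata and generator provenance. The sidecar sits next to the
# HDF5 file with the extension swapped for .json.

sidecar_path <- function(path) paste0(sub("\\.h5$", "", path), ".json")

#' Save / load an epoch set
#'
#' The container is an HDF5 file with datasets `/data`
#' (epochs x channels x samples, 64-bit float) and `/labels` (int), plus a
#' JSON sidecar (same stem, `.json`) holding `sampling_rate`,
#' `channel_names`, `class_names` and the generating spec (provenance,
#' including the seed). The round trip is lossless.
#'
#' @param es An [epoch_set()].
#' @param path Path to the `.h5` file to write/read.
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns the
#'   `epoch_set`.
#' @export
save_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(es$data, path, "data")
  rhdf5::h5write(as.integer(es$labels), path, "labels")
  rhdf5::H5close()
  meta <- list(sampling_rate = es$sampling_rate,
               channel_names = es$channel_names,
               class_names = es$class_names,
               provenance = es$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path))
    stop("epoch container not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for ", path, " (expected ", sc, ")", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("sampling_rate", "channel_names"))
    if (is.null(meta[[key]]))
      stop("epoch container sidecar is missing metadata key '", key, "'", call. = FALSE)
  dat <- tryCatch({
    d <- rhdf5::h5read(path, "data")
    l <- rhdf5::h5read(path, "labels")
    rhdf5::H5close()
    list(d = d, l = l)
  }, error = function(e) {
    rhdf5::H5close()
    stop("corrupt or unreadable epoch container ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  epoch_set(data = dat$d, labels = as.integer(dat$l),
            sampling_rate = meta$sampling_rate,
            channel_names = meta$channel_names,
            class_names = meta$class_names,
            provenance = if (is.data.frame(prov)) as.list(prov) else prov)
}
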