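# Plain-text I/O: single-column signals with a JSON sidecar, and spectral
# data as JSON documents.

#' Write / read a single-channel signal as delimited text
#'
#' The signal is written one sample per line; metadata (sampling rate,
#' units, seed, ground truth such as burst times) goes into a JSON sidecar
#' at `<path>.json`.
#'
#' @param x Numeric signal, or an `"ecog_sim"` (whose burst ground truth is
#'   carried into the sidecar).
#' @param path Signal file path.
#' @param fs Sampling rate in Hz (taken from an `"ecog_sim"` automatically).
#' @param units Unit label stored in the sidecar.
#' @param meta Extra metadata list merged into the sidecar.
#' @return `write_signal` returns `path` invisibly; `read_signal` returns a
#'   list with `signal`, `fs` and `meta`.
#' @export
write_signal <- function(x, path, fs = NULL, units = "a.u.", meta = list()) {
  if (inherits(x, "ecog_sim")) {
    meta <- c(meta, list(bursts = x$bursts, seed = x$config$seed,
                         config = unclass(x$config)))
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) stop("fs is required")
  writeLines(formatC(x, format = "g", digits = 10), path)
  side <- c(list(fs = fs, units = units, n = length(x)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  x <- as.numeric(readLines(path))
  side_path <- paste0(path, ".json")
  meta <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  else list()
  list(signal = x, fs = meta$fs, meta = meta)
}

#' Write / read spectral data as JSON
#'
#' @param x A [csd()].
#' @param path File path.
#' @return `write_csd` returns `path` invisibly; `read_csd` a [csd()].
#' @export
write_csd <- function(x, path) {
  stopifnot(inherits(x, "csd"))
  doc <- list(freqs = x$freqs,
              conditions = colnames(x$spectra),
              spectra = apply(x$spectra, 2, identity, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- do.call(cbind, doc$spectra[doc$conditions])
  csd(doc$freqs, sp)
}
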