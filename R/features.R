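# Data-feature pipeline: band-pass filter -> Hilbert envelope -> 500 ms
# epochs -> envelope-area percentile classification -> random epoch
# selection -> per-condition autoregressive spectra.

#' Beta-band Butterworth filter
#'
#' Applies a second-order Butterworth band-pass (15--35 Hz) forward and
#' backward (zero-phase, so envelope timing is unbiased; the effective
#' magnitude response is squared).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz, at least 200 (twice a comfortable margin
#'   above the upper band edge).
#' @param band Length-2 pass band in Hz.
#' @param order Filter order (of the underlying one-pass design).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_beta <- function(x, fs, band = c(15, 35), order = 2L) {
  if (fs < 200) stop("sampling rate too low for the 15-35 Hz band: ", fs)
  if (length(x) < fs) stop("signal shorter than 1 s")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal, computed by zeroing negative
#' frequencies in the discrete Fourier transform.
#'
#' @param x Numeric (band-pass filtered) signal.
#' @return Non-negative envelope, same length as `x`.
#' @export
beta_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Cut an envelope into epochs and classify beta conditions
#'
#' Divides the envelope into non-overlapping epochs (trailing remainder
#' dropped), computes each epoch's envelope area (sum of samples times the
#' sampling interval), and labels epochs strictly below the lower area
#' percentile as low beta (LB) and strictly above the upper percentile as
#' high beta (HB); epochs in between are discarded. Percentiles use linear
#' interpolation (quantile type 7) and are computed per recording.
#'
#' @param envelope Non-negative envelope signal.
#' @param fs Sampling rate in Hz.
#' @param epoch_ms Epoch length in milliseconds (500 by default).
#' @param lo,hi Lower/upper percentile thresholds as probabilities
#'   (default 0.05 and 0.95).
#' @param signal Optional raw (or filtered) signal of the same length whose
#'   samples are carried into the epochs for later spectral estimation;
#'   defaults to the envelope itself.
#' @return An object of class `"epoch_set"`: list with `fs`, `epoch_len`
#'   (samples), `areas` (all epochs), `labels` (factor `LB`/`HB`/`mid`),
#'   `epochs` (list of labeled epochs with `label`, `samples`,
#'   `envelope_area`, `index`), and the thresholds used.
#' @export
segment_epochs <- function(envelope, fs, epoch_ms = 500, lo = 0.05,
                           hi = 0.95, signal = NULL) {
  if (any(envelope < 0)) stop("envelope must be non-negative")
  if (is.null(signal)) signal <- envelope
  stopifnot(length(signal) == length(envelope))
  len <- round(epoch_ms / 1000 * fs)
  n_ep <- floor(length(envelope) / len)
  if (n_ep < 20L) stop("need at least 20 whole epochs, have ", n_ep)
  idx <- seq_len(n_ep * len)
  em <- matrix(envelope[idx], nrow = len)
  areas <- colSums(em) / fs
  if (max(areas) - min(areas) <= 0)
    stop("degenerate envelope: zero spread in epoch areas")
  q <- stats::quantile(areas, c(lo, hi), names = FALSE, type = 7)
  labels <- rep("mid", n_ep)
  labels[areas < q[1]] <- "LB"
  labels[areas > q[2]] <- "HB"
  sm <- matrix(signal[idx], nrow = len)
  keep <- which(labels != "mid")
  epochs <- lapply(keep, function(i)
    list(label = labels[i], samples = sm[, i], envelope_area = areas[i],
         index = i))
  structure(list(fs = fs, epoch_len = len, areas = areas,
                 labels = factor(labels, levels = c("LB", "mid", "HB")),
                 thresholds = c(lo = q[1], hi = q[2]), epochs = epochs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  nl <- sum(vapply(x$epochs, function(e) e$label == "LB", logical(1)))
  nh <- length(x$epochs) - nl
  cat(sprintf("epoch set: %d epochs of %d samples at %g Hz (%d LB, %d HB)\n",
              length(x$areas), x$epoch_len, x$fs, nl, nh))
  invisible(x)
}

#' Randomly select epochs per condition
#'
#' Draws a uniformly random subset of `n` epochs from each condition,
#' reproducibly under `seed` (the RNG state of the session is restored on
#' exit).
#'
#' @param es An `"epoch_set"`.
#' @param n Epochs per condition (5 by default).
#' @param seed Integer seed.
#' @return An `"epoch_set"` containing only the selected epochs.
#' @export
select_epochs <- function(es, n = 5L, seed = 1L) {
  stopifnot(inherits(es, "epoch_set"))
  lab <- vapply(es$epochs, function(e) e$label, character(1))
  counts <- c(LB = sum(lab == "LB"), HB = sum(lab == "HB"))
  if (any(counts < n))
    stop(sprintf("fewer than %d epochs in a condition (LB: %d, HB: %d)",
                 n, counts[["LB"]], counts[["HB"]]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- c(sample(which(lab == "LB"), n), sample(which(lab == "HB"), n))
  out <- es
  out$epochs <- es$epochs[sort(pick)]
  out
}

# one-sided AR power spectral density on an arbitrary frequency grid
.ar_psd <- function(x, fs, freqs, order) {
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  z <- exp(-2i * pi * outer(freqs / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(z %*% a))^2
  2 * fit$var.pred / fs / denom
}

#' Per-condition spectral density of selected epochs
#'
#' Estimates each epoch's power spectral density by autoregressive (Burg)
#' spectral estimation of fixed order, evaluated on the requested frequency
#' grid, and averages within condition. Autoregressive estimation is used
#' because 500 ms epochs make raw periodograms unusably coarse (2 Hz
#' resolution).
#'
#' @param es An `"epoch_set"` (typically after [select_epochs()]).
#' @param freqs Frequency grid in Hz.
#' @param order AR model order (default 16).
#' @return A [csd()] with one column per condition present.
#' @export
condition_spectra <- function(es, freqs = seq(4, 48, by = 0.5), order = 16L) {
  stopifnot(inherits(es, "epoch_set"))
  if (max(freqs) > es$fs / 2) stop("frequency grid beyond Nyquist")
  if (es$epoch_len < es$fs / min(freqs))
    stop("epochs shorter than one period of the lowest requested frequency")
  lab <- vapply(es$epochs, function(e) e$label, character(1))
  conds <- intersect(c("LB", "HB"), unique(lab))
  if (length(conds) == 0L) stop("no labeled epochs")
  spectra <- sapply(conds, function(cc) {
    ps <- vapply(es$epochs[lab == cc],
                 function(e) .ar_psd(e$samples, es$fs, freqs, order),
                 numeric(length(freqs)))
    rowMeans(ps)
  })
  csd(freqs, spectra)
}

#' Full feature-extraction chain
#'
#' Band-pass filters a single-channel recording to the beta band, computes
#' the Hilbert envelope, cuts 500 ms epochs, classifies the envelope-area
#' percentile tails into low/high beta conditions, randomly selects `n`
#' epochs per condition and returns their average spectra. Spectra are
#' estimated from the raw (unfiltered) epochs.
#'
#' @param x Numeric single-channel signal.
#' @param fs Sampling rate in Hz.
#' @param freqs Frequency grid for the output spectra.
#' @param n Epochs selected per condition.
#' @param seed Selection seed.
#' @param ... Passed to [segment_epochs()].
#' @return List with `csd` (a [csd()]), `epochs` (the selected
#'   `"epoch_set"`) and `all_epochs` (the full classified set).
#' @export
extract_features <- function(x, fs, freqs = seq(4, 48, by = 0.5), n = 5L,
                             seed = 1L, ...) {
  filt <- bandpass_beta(x, fs)
  env <- beta_envelope(filt)
  es <- segment_epochs(env, fs, signal = x, ...)
  sel <- select_epochs(es, n = n, seed = seed)
  list(csd = condition_spectra(sel, freqs), epochs = sel, all_epochs = es)
}
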