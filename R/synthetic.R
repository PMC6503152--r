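# Synthetic-data generators: bursty ECoG-like signals for the feature
# pipeline, stochastic circuit simulations (the cross-validation oracle for
# the linearized spectra) and model-based group datasets with known ground
# truth.

# real-valued noise with prescribed one-sided PSD G(f) (units^2/Hz),
# synthesized in the frequency domain; G is a function of f > 0. Gaussian
# draws are interleaved per frequency (real, imaginary) in ascending
# frequency order, so that for a fixed duration and seed the realized
# continuous path is invariant to the sampling rate wherever G vanishes
# above a common cutoff.
.noise_from_psd <- function(n, fs, G) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- sqrt(pmax(G(f), 0) * fs * n / 4)
  z <- stats::rnorm(2 * nf)
  Z <- complex(real = z[seq(1, 2 * nf, 2)],
               imaginary = z[seq(2, 2 * nf, 2)]) * amp
  X <- complex(real = numeric(n))
  X[2:(nf + 1)] <- Z
  if (n %% 2 == 0) X[nf + 1] <- sqrt(pmax(G(f[nf]), 0) * fs * n / 2) *
      stats::rnorm(1)
  X[n:(n - nf + 2)] <- Conj(X[2:(nf)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Configuration for the bursty ECoG generator
#'
#' Defaults emulate intermittent beta bursts riding on a 1/f background at
#' the standard 1000 Hz sampling rate: a 25 Hz carrier gated by a two-state
#' Markov (telegraph) process with on-rate `burst_rate` and mean burst
#' length `burst_duration`, at `burst_amplitude` times the background's
#' beta-band RMS.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Seconds (at least 30 so that epoching yields enough
#'   epochs).
#' @param carrier_freq Burst carrier frequency in the 15--35 Hz band.
#' @param burst_rate Burst onsets per second of non-burst time.
#' @param burst_duration Mean burst length, seconds.
#' @param burst_amplitude Carrier amplitude as a multiple of the
#'   background beta-band RMS; 0 disables bursts.
#' @param background_exponent Spectral slope of the 1/f^a background.
#' @param seed Integer seed.
#' @return List of class `"burst_config"`.
#' @export
burst_config <- function(fs = 1000, duration = 120, carrier_freq = 25,
                         burst_rate = 0.8, burst_duration = 0.3,
                         burst_amplitude = 4, background_exponent = 1,
                         seed = 1L) {
  stopifnot(fs > 0, duration >= 30, carrier_freq >= 15, carrier_freq <= 35,
            burst_rate > 0, burst_duration > 0, burst_amplitude >= 0)
  structure(list(fs = fs, duration = duration, carrier_freq = carrier_freq,
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 burst_amplitude = burst_amplitude,
                 background_exponent = background_exponent,
                 seed = as.integer(seed)),
            class = "burst_config")
}

#' Generate a bursty ECoG-like signal
#'
#' A 1/f^a background plus an amplitude-modulated beta-band carrier whose
#' envelope is a smoothed two-state Markov gate; burst onset/offset times
#' are returned as ground truth. Deterministic under the config seed.
#'
#' @param cfg A [burst_config()].
#' @return List of class `"ecog_sim"`: `signal`, `fs`, `time`, `bursts`
#'   (data frame of onset/offset seconds), `gate` (the smoothed envelope
#'   gate) and `config`.
#' @export
#' @examples
#' x <- generate_bursty_ecog(burst_config(duration = 30))
generate_bursty_ecog <- function(cfg) {
  stopifnot(inherits(cfg, "burst_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n <- round(cfg$fs * cfg$duration)
  a <- cfg$background_exponent
  bg <- .noise_from_psd(n, cfg$fs, function(f) 1 / f^a)
  bg <- bg / stats::sd(bg)
  # two-state telegraph gate
  gate <- numeric(n)
  onsets <- offsets <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, cfg$burst_rate)
    if (t >= cfg$duration) break
    len <- stats::rexp(1, 1 / cfg$burst_duration)
    i0 <- max(1L, round(t * cfg$fs)); i1 <- min(n, round((t + len) * cfg$fs))
    gate[i0:i1] <- 1
    onsets <- c(onsets, t); offsets <- c(offsets, min(t + len, cfg$duration))
    t <- t + len
  }
  # smooth gate edges (50 ms raised cosine) to avoid spectral splatter
  ramp <- round(0.05 * cfg$fs)
  if (ramp > 1) {
    k <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    k <- c(k, rev(k)) / sum(c(k, rev(k)))
    gate <- as.numeric(stats::filter(c(rep(gate[1], ramp), gate,
                                       rep(gate[n], ramp)), k, sides = 2))
    gate <- gate[(ramp + 1):(ramp + n)]
    gate[is.na(gate)] <- 0
  }
  # carrier amplitude relative to the background's beta-band RMS
  sd_beta <- stats::sd(bandpass_beta(bg, cfg$fs))
  carrier <- sin(2 * pi * cfg$carrier_freq * seq_len(n) / cfg$fs +
                   stats::runif(1, 0, 2 * pi))
  signal <- bg + cfg$burst_amplitude * sd_beta * gate * carrier
  structure(list(signal = signal, fs = cfg$fs,
                 time = seq_len(n) / cfg$fs,
                 bursts = data.frame(onset = onsets, offset = offsets),
                 gate = gate, config = cfg),
            class = "ecog_sim")
}

#' @export
print.ecog_sim <- function(x, ...) {
  cat(sprintf("synthetic ECoG: %g s at %g Hz, %d bursts\n",
              x$config$duration, x$fs, nrow(x$bursts)))
  invisible(x)
}

#' Stochastic simulation of the thalamocortical circuit
#'
#' Integrates the delayed nonlinear circuit with a fixed-step scheme
#' (compiled, delay ring buffers; default step 0.1 ms) driven by
#' exogenous noise at MP and REL with the white-plus-pink spectrum assumed
#' by the forward model (`G_u(f) = exp(alpha_s) + exp(beta_s)/f`). The
#' observed channel is the gain-scaled J-weighted sum of SP, MP, DP
#' voltages plus channel noise with spectrum `G_n`. This is the
#' cross-validation oracle for [predict_csd()].
#'
#' @param spec A [tc_model()].
#' @param params A `"tc_params"`.
#' @param duration Seconds of retained output.
#' @param fs Output sampling rate, Hz.
#' @param seed Integer seed.
#' @param dt Integration step, seconds.
#' @param condition Condition whose couplings to use.
#' @param burn_in Seconds of discarded transient.
#' @param noise_scale Multiplier on the input noise amplitude (1 =
#'   the spectrum assumed by the forward model; 0 gives deterministic
#'   dynamics).
#' @param channel_noise Add channel noise with spectrum `G_n` to the
#'   observed series.
#' @param input_cutoff Band limit of the synthesized exogenous path, Hz;
#'   the realized path is then invariant to the integration step.
#' @return List of class `"tc_sim"`: `time`, `v` (samples x 6 voltages),
#'   `observed`, `fs`, `dt`.
#' @export
simulate_timeseries <- function(spec, params, duration = 60, fs = 1000,
                                seed = 1L, dt = 1e-4,
                                condition = "LB", burn_in = 2,
                                noise_scale = 1, channel_noise = TRUE,
                                input_cutoff = 500) {
  stopifnot(inherits(spec, "tc_model"), inherits(params, "tc_params"))
  lin <- linearize(spec, params, condition = condition)
  if (!lin$stable) stop("unstable regime: simulation refused")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conn <- build_connectivity(spec, params, condition)
  keep_every <- round(1 / (fs * dt))
  if (abs(keep_every - 1 / (fs * dt)) > 1e-9)
    stop("1/(fs*dt) must be an integer")
  ntot <- round((duration + burn_in) / dt)
  # the exogenous path is band-limited at a fixed cutoff so that the same
  # seed realizes the same continuous input at any integration step (the
  # circuit attenuates input far above the band by orders of magnitude)
  cutoff <- min(input_cutoff, 0.5 / dt)
  Gu <- function(f) ifelse(f <= cutoff, .input_psd(params, f), 0)
  stream_seeds <- sample.int(.Machine$integer.max, 3)
  gen_stream <- function(k, nn, sr, G) {
    set.seed(stream_seeds[k])
    .noise_from_psd(nn, sr, G)
  }
  inp <- cbind(noise_scale * gen_stream(1, ntot, 1 / dt, Gu),
               noise_scale * gen_stream(2, ntot, 1 / dt, Gu))
  lag <- matrix(as.integer(round(conn$D / dt)), 6, 6)
  fp <- find_fixed_point(spec, params, condition = condition)
  R <- c(rep(params$R_mmc, 4), rep(params$R_tcr, 2))
  res <- integrate_tc_cpp(conn$C, lag, params$T, R, inp,
                          input_rows = c(2L, 5L), dt = dt,
                          keep_every = keep_every,
                          v0 = fp[1:6], vd0 = fp[7:12])
  v <- res$v
  nb <- round(burn_in * fs)
  v <- v[(nb + 1):nrow(v), , drop = FALSE]
  colnames(v) <- .pop_names
  obs <- params$L * as.vector(v[, 1:3] %*%
                                c(params$J[["SP"]], params$J[["MP"]],
                                  params$J[["DP"]]))
  if (channel_noise) {
    Gn <- function(f) .channel_psd(params, f)
    obs <- obs + noise_scale * gen_stream(3, length(obs), fs, Gn)
  }
  structure(list(time = seq_len(nrow(v)) / fs, v = v, observed = obs,
                 fs = fs, dt = dt, condition = condition, seed = seed),
            class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat(sprintf("circuit simulation: %g s at %g Hz (step %g ms, %s)\n",
              length(x$observed) / x$fs, x$fs, 1000 * x$dt, x$condition))
  invisible(x)
}

#' Welch-averaged power spectral density
#'
#' One-sided PSD by averaging Hann-windowed, overlapping segment
#' periodograms; used to compare simulated time series against the
#' linearized spectral prediction.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in samples (default 2 s).
#' @param overlap Fractional overlap between segments.
#' @return Data frame with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = 2 * fs, overlap = 0.5) {
  seg_len <- round(seg_len)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  if (length(starts) < 1L) stop("signal shorter than one segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  U <- sum(w^2)
  nf <- floor(seg_len / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[2:(nf + 1)])^2)
  }
  psd <- 2 * acc / (length(starts) * fs * U)
  data.frame(freq = seq_len(nf) * fs / seg_len, psd = psd)
}

#' Generate a model-based two-condition group dataset
#'
#' For each subject, free-parameter deviations are drawn around the group
#' truth (zero except the supplied condition effects) with standard
#' deviation `subject_sd`, both conditions' spectra are predicted, and
#' multiplicative log-normal observation noise of standard deviation
#' `obs_noise` (on the log spectra) is applied. Unstable draws are redrawn
#' (up to 10 attempts per subject). The ground truth is returned alongside
#' the data.
#'
#' @param spec A [tc_model()].
#' @param true_B Named numeric vector of group-level condition effects
#'   (names are B parameter names or edge labels of `spec`).
#' @param n_subjects Number of subjects (at least 2).
#' @param subject_sd Between-subject SD of all free-parameter deviations.
#' @param obs_noise SD of iid Gaussian noise added to log spectra.
#' @param seed Integer seed.
#' @param freqs Frequency grid.
#' @param priors Priors used for expansion (defaults to `tc_priors(spec)`).
#' @param vary Parameter groups receiving between-subject variability
#'   (default: condition effects and coupling strengths).
#' @return List of class `"group_dataset"`: `data` (list of [csd()]),
#'   `truth` (list with per-subject `theta`, `true_B`, redraw counts),
#'   `priors`, `spec`.
#' @export
generate_group_dataset <- function(spec, true_B, n_subjects, subject_sd = 0.1,
                                   obs_noise = 0, seed = 1L,
                                   freqs = seq(4, 48, by = 0.5),
                                   priors = tc_priors(spec),
                                   vary = c("B", "gamma_mmc", "gamma_tcr",
                                            "lambda")) {
  stopifnot(inherits(spec, "tc_model"), n_subjects >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tab <- priors$table
  # allow edge labels for true_B
  bn <- names(true_B)
  is_edge <- bn %in% tab$label[tab$group == "B"]
  bn[is_edge] <- tab$name[tab$group == "B"][match(bn[is_edge],
                                                  tab$label[tab$group == "B"])]
  names(true_B) <- bn
  if (!all(bn %in% tab$name[tab$group == "B"]))
    stop("true_B entries must name condition effects of this model")
  group_truth <- stats::setNames(numeric(nrow(tab)), tab$name)
  group_truth[bn] <- true_B
  vary_names <- tab$name[tab$group %in% vary]
  data <- vector("list", n_subjects)
  thetas <- vector("list", n_subjects)
  redraws <- integer(n_subjects)
  for (i in seq_len(n_subjects)) {
    for (attempt in 1:10) {
      th <- group_truth
      th[vary_names] <- th[vary_names] +
        stats::rnorm(length(vary_names), 0, subject_sd)
      th <- th[setdiff(names(th), "hE")]
      x <- tryCatch(
        predict_csd(spec, expand_params(priors, th), freqs, "both"),
        error = function(e) NULL)
      if (!is.null(x)) break
      redraws[i] <- redraws[i] + 1L
    }
    if (is.null(x))
      stop("could not draw a stable subject after 10 attempts (subject ",
           i, ")")
    if (obs_noise > 0)
      x$spectra <- x$spectra * exp(matrix(
        stats::rnorm(length(x$spectra), 0, obs_noise), nrow(x$spectra)))
    data[[i]] <- x
    thetas[[i]] <- th
  }
  structure(list(data = data,
                 truth = list(theta = thetas, true_B = true_B,
                              redraws = redraws, seed = seed,
                              subject_sd = subject_sd,
                              obs_noise = obs_noise),
                 priors = priors, spec = spec),
            class = "group_dataset")
}
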