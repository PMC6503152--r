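fs <- 1000

test_that("the beta filter passes 25 Hz, rejects 2 Hz, and concentrates
          white noise in the band", {
  t <- seq_len(10 * fs) / fs
  mid <- (2 * fs):(8 * fs)   # away from filter edges
  tone25 <- sin(2 * pi * 25 * t)
  y <- bandpass_beta(tone25, fs)
  amp <- sqrt(2) * sd(y[mid])
  expect_lt(abs(amp - 1), 0.05)
  tone2 <- sin(2 * pi * 2 * t)
  y2 <- bandpass_beta(tone2, fs)
  expect_lt(sqrt(2) * sd(y2[mid]), 0.10)
  # magnitude-response oracle for the 2 Hz attenuation (squared response
  # because filtering is forward-backward)
  bf <- signal::butter(2, c(15, 35) / (fs / 2), type = "pass")
  H2 <- Mod(signal::freqz(bf$b, bf$a, 2 * pi * 2 / fs)$h)^2
  expect_lt(H2, 0.10)
  set.seed(3)
  wn <- rnorm(60 * fs)
  yw <- bandpass_beta(wn, fs)
  w <- welch_psd(yw, fs, seg_len = 2 * fs)
  mass_band <- sum(w$psd[w$freq >= 15 & w$freq <= 35])
  expect_gt(mass_band / sum(w$psd), 0.80)
  expect_error(bandpass_beta(rnorm(1000), fs = 60), "too low")
})

test_that("the Hilbert envelope recovers constant and modulated amplitudes", {
  t <- seq_len(5 * fs) / fs
  mid <- (fs):(4 * fs)
  A <- 2.3
  env <- beta_envelope(A * sin(2 * pi * 25 * t))
  expect_true(all(abs(env[mid] - A) / A < 0.02))
  expect_true(all(env >= 0))
  # known-modulator construction
  mo <- 1 + 0.5 * sin(2 * pi * 1.5 * t)
  env2 <- beta_envelope(mo * sin(2 * pi * 25 * t))
  expect_gt(cor(env2[mid], mo[mid]), 0.99)
  expect_identical(beta_envelope(numeric(10)), numeric(10))
  expect_error(beta_envelope(numeric(0)), "empty")
})

test_that("epoch classification matches a brute-force percentile oracle", {
  # construct an envelope with prescribed per-epoch areas
  make_env <- function(areas, len = 500) rep(areas, each = len) / (len / fs)
  # 100 epochs with strictly increasing areas -> 5 LB and 5 HB
  areas <- seq(1, 100)
  es <- segment_epochs(make_env(areas), fs)
  lab <- vapply(es$epochs, function(e) e$label, character(1))
  expect_equal(sum(lab == "LB"), 5L)
  expect_equal(sum(lab == "HB"), 5L)
  # brute-force oracle on the recovered areas
  q <- quantile(es$areas, c(0.05, 0.95), names = FALSE)
  expect_equal(sum(lab == "LB"), sum(es$areas < q[1]))
  expect_equal(sum(lab == "HB"), sum(es$areas > q[2]))
  expect_identical(which(es$labels == "LB"), which(es$areas < q[1]))
  # 20 distinct epochs -> exactly the minimum-area epoch is LB
  set.seed(8)
  areas20 <- sample(20)
  es20 <- segment_epochs(make_env(areas20), fs)
  lab20 <- vapply(es20$epochs, function(e) e$label, character(1))
  expect_equal(sum(lab20 == "LB"), 1L)
  expect_equal(es20$epochs[[which(lab20 == "LB")[1]]]$index,
               which.min(areas20))
  # degenerate (constant) envelope errors
  expect_error(segment_epochs(make_env(rep(3, 30)), fs), "degenerate")
  # random areas: counts equal the brute-force computation, and the tails
  # hold at most ceiling(0.05 N) epochs
  for (N in c(40, 77, 240)) {
    a <- runif(N)
    esr <- segment_epochs(make_env(a), fs)
    qr <- quantile(esr$areas, c(0.05, 0.95), names = FALSE)
    labr <- vapply(esr$epochs, function(e) e$label, character(1))
    expect_equal(sum(labr == "LB"), sum(esr$areas < qr[1]))
    expect_equal(sum(labr == "HB"), sum(esr$areas > qr[2]))
    expect_lte(sum(labr == "LB"), ceiling(0.05 * N))
    expect_lte(sum(labr == "HB"), ceiling(0.05 * N))
  }
})

test_that("epochs have the exact 500 ms length and drop the remainder", {
  env <- abs(rnorm(30 * fs + 123)) + 0.1
  es <- segment_epochs(env, fs)
  expect_equal(es$epoch_len, 500L)
  expect_length(es$areas, 60L)
  expect_true(all(vapply(es$epochs, function(e) length(e$samples),
                         integer(1)) == 500L))
})

test_that("epoch selection is seeded, uniform and errors on shortfall", {
  env <- rep(seq(1, 100), each = 500) / 500 * fs
  es <- segment_epochs(env, fs)
  s1 <- select_epochs(es, n = 5, seed = 42)
  s2 <- select_epochs(es, n = 5, seed = 42)
  expect_identical(s1$epochs, s2$epochs)
  lab <- vapply(s1$epochs, function(e) e$label, character(1))
  expect_equal(sum(lab == "LB"), 5L)
  expect_equal(sum(lab == "HB"), 5L)
  # n equal to the available count returns every epoch
  sall <- select_epochs(es, n = 5, seed = 7)
  expect_length(sall$epochs, 10L)
  expect_error(select_epochs(es, n = 6), "fewer than 6")
})

test_that("condition spectra localize tones, flatten white noise and are
          permutation-invariant", {
  t <- seq_len(500) / fs
  mk_es <- function(samples_list, labels) {
    eps <- Map(function(s, l, i) list(label = l, samples = s,
                                      envelope_area = 1, index = i),
               samples_list, labels, seq_along(labels))
    structure(list(fs = fs, epoch_len = 500L,
                   areas = rep(1, length(eps)),
                   labels = factor(labels, levels = c("LB", "mid", "HB")),
                   thresholds = c(lo = 0, hi = 2), epochs = eps),
              class = "epoch_set")
  }
  tone <- lapply(1:4, function(i) sin(2 * pi * 25 * t + i))
  x <- condition_spectra(mk_es(tone, rep("LB", 4)), seq(10, 45, 0.5))
  expect_equal(x$freqs[which.max(x$spectra[, "LB"])], 25, tolerance = 0.05)
  set.seed(5)
  wn <- lapply(1:50, function(i) rnorm(500))
  xw <- condition_spectra(mk_es(wn, rep("HB", 50)), seq(10, 45, 1))
  band <- xw$spectra[xw$freqs >= 15 & xw$freqs <= 35, "HB"]
  expect_lt(max(band) / min(band), 3)
  # permutation invariance of the within-condition average
  perm <- sample(50)
  xp <- condition_spectra(mk_es(wn[perm], rep("HB", 50)), seq(10, 45, 1))
  expect_equal(xw$spectra, xp$spectra, tolerance = 1e-12)
  expect_error(condition_spectra(mk_es(tone, rep("LB", 4)), seq(1, 45, 1)),
               "shorter")
})

test_that("the full chain labels burst-bearing epochs as high beta with
          precision at least 0.9", {
  x <- generate_bursty_ecog(burst_config(duration = 120, seed = 14))
  fe <- extract_features(x$signal, x$fs, seed = 2)
  lab <- vapply(fe$all_epochs$epochs, function(e) e$label, character(1))
  idx <- vapply(fe$all_epochs$epochs, function(e) e$index, integer(1))
  hb_idx <- idx[lab == "HB"]
  # an epoch "bears a burst" if it overlaps any ground-truth burst interval
  overlaps <- function(i) {
    t0 <- (i - 1) * 0.5; t1 <- i * 0.5
    any(x$bursts$onset < t1 & x$bursts$offset > t0)
  }
  prec <- mean(vapply(hb_idx, overlaps, logical(1)))
  expect_gte(prec, 0.9)
})
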