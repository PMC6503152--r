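test_that("fixed point is the origin at defaults and matches long-horizon
          integration under constant drive", {
  fp <- find_fixed_point(win_spec, default_params)
  expect_equal(fp, rep(0, 12), tolerance = 1e-12)
  # ODE integration oracle: settle the driven system and compare
  drive <- 0.4
  fp_d <- find_fixed_point(win_spec, default_params, drive = drive)
  expect_lt(max(abs(dynamics(fp_d,
                             build_connectivity(win_spec, default_params)$input * drive,
                             default_params, win_spec))), 1e-10)
  rhs <- function(t, y, parms)
    list(dynamics(y, parms, default_params, win_spec))
  inp <- build_connectivity(win_spec, default_params)$input * drive
  out <- deSolve::ode(rep(0, 12), c(0, 2), rhs, inp)
  expect_equal(unname(out[2, 2:13]), fp_d, tolerance = 1e-5)
})

test_that("gross coupling inflation is reported as instability", {
  th <- theta_template(win_priors)
  th[win_priors$table$group %in% c("gamma_mmc", "gamma_tcr", "lambda")] <- log(100)
  p <- expand_params(win_priors, th)
  expect_error(predict_csd(win_spec, p, seq(4, 48, 1)), "unstable")
  expect_false(linearize(win_spec, p)$stable)
})

test_that("zero delays make the delay-corrected matrix equal the Jacobian", {
  pr0 <- win_priors
  pr0$delays <- c(intrinsic = 0, extrinsic = 0)
  lin <- linearize(win_spec, expand_params(pr0))
  expect_equal(lin$A_eff, lin$jacobian, tolerance = 1e-14)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(11)
  for (rep in 1:3) {
    st <- c(rnorm(6, 0, 0.3), rnorm(6, 0, 0.3))
    lin <- linearize(win_spec, default_params, at = st)
    h <- 1e-6
    Jfd <- matrix(0, 12, 12)
    for (j in 1:12) {
      e <- rep(0, 12); e[j] <- h
      Jfd[, j] <- (dynamics(st + e, 0, default_params, win_spec) -
                     dynamics(st - e, 0, default_params, win_spec)) / (2 * h)
    }
    expect_equal(lin$jacobian, Jfd,
                 tolerance = 1e-6 * max(abs(lin$jacobian)))
  }
})

test_that("small delays: delay-corrected eigenfrequency matches a delayed
          simulation", {
  # delayed-ODE oracle: simulate the delayed *linear* system and compare its
  # dominant oscillation frequency with the first-order corrected matrix
  pr <- win_priors
  pr$delays <- c(intrinsic = 0.5, extrinsic = 0.5)  # small delays, ms
  p <- expand_params(pr)
  lin <- linearize(win_spec, p)
  ev <- lin$eigenvalues
  f_pred <- abs(Im(ev[which.max(Re(ev))])) / (2 * pi)
  A <- lin$jacobian
  Dfull <- matrix(0, 12, 12); Dfull[7:12, 1:6] <- lin$D
  rhs <- function(t, y, parms) {
    # elementwise delayed state: x_j(t - D_ij) differs per row
    dy <- numeric(12)
    for (i in 1:12) {
      acc <- 0
      for (j in 1:12) {
        if (A[i, j] != 0) {
          d <- Dfull[i, j]
          xj <- if (d > 0 && t > d) deSolve::lagvalue(t - d, j) else
            if (d > 0) 0 else y[j]
          acc <- acc + A[i, j] * xj
        }
      }
      dy[i] <- acc
    }
    list(dy)
  }
  y0 <- c(rep(0.01, 6), rep(0, 6))
  times <- seq(0, 1.5, by = 5e-4)
  out <- deSolve::dede(y0, times, rhs, NULL)
  x <- out[times > 0.2, 2]  # SP voltage after transient
  # dominant frequency from the periodogram
  sp <- Mod(fft(x - mean(x)))^2
  nf <- floor(length(x) / 2)
  fgrid <- seq_len(nf) / (length(x) * 5e-4)
  f_sim <- fgrid[which.max(sp[2:(nf + 1)])]
  expect_equal(f_sim, f_pred, tolerance = 0.08)
})

test_that("predicted spectra are positive and conditions coincide at B = 0", {
  x <- predict_csd(win_spec, default_params, seq(4, 48, 0.5))
  expect_true(all(is.finite(x$spectra)) && all(x$spectra > 0))
  expect_equal(x$spectra[, "LB"], x$spectra[, "HB"], tolerance = 1e-14)
})

test_that("with the gain off the observed spectrum is the channel noise", {
  th <- theta_template(win_priors)
  th["L"] <- -60  # gain exp(-60): observation switched off
  p <- expand_params(win_priors, th)
  f <- seq(4, 48, 0.5)
  x <- predict_csd(win_spec, p, f, condition = "LB")
  gn <- 1e-5 * (exp(p$alpha_c) + exp(p$beta_c) / f)
  expect_equal(unname(x$spectra[, "LB"]), gn, tolerance = 1e-8)
})

test_that("a zero-frequency grid point is rejected", {
  expect_error(predict_csd(win_spec, default_params, seq(0, 48, 1)),
               "positive")
})

test_that("spectra vary continuously with parameters", {
  f <- seq(4, 48, 1)
  base <- predict_csd(win_spec, default_params, f, "LB")$spectra[, 1]
  th <- theta_template(win_priors)
  for (nm in c("G2", "A1", "T1", "Rm")) {
    th[] <- 0; th[nm] <- 1e-4
    pert <- predict_csd(win_spec, expand_params(win_priors, th), f,
                        "LB")$spectra[, 1]
    rel <- max(abs(pert - base) / base)
    expect_lt(rel, 0.05)  # bounded finite-difference sensitivity
  }
})

test_that("every population has a beta-band spectral peak at the default
          operating point, in both conditions", {
  x <- predict_csd(win_spec, default_params, seq(4, 48, 0.5), source = TRUE)
  for (cc in c("LB", "HB")) for (pp in 1:6) {
    s <- x$source[[cc]][, pp]
    i <- which.max(s)
    expect_gt(x$freqs[i], 15)
    expect_lt(x$freqs[i], 35)
    # a genuine local maximum, not a grid-edge artefact
    expect_gt(s[i], s[1])
    expect_gt(s[i], s[length(s)])
  }
})

test_that("band power counts, integrates and scales as documented", {
  flat <- csd(1:50, matrix(1, 50, 1, dimnames = list(NULL, "LB")))
  expect_equal(unname(band_power(flat, c(15, 35), method = "sum")), 21)
  expect_equal(unname(band_power(flat, c(15, 35), method = "trapz")), 20)
  x <- predict_csd(win_spec, default_params, seq(4, 48, 0.5))
  x2 <- x; x2$spectra <- 2 * x2$spectra
  expect_equal(band_power(x2), 2 * band_power(x))
  expect_error(band_power(x, c(1, 35)), "outside")
  # positive modulation pattern raises high-beta band power
  xp <- make_dataset(win_spec, win_priors, pattern_theta(win_priors))
  bp <- band_power(xp)
  expect_gt(bp[["HB"]], bp[["LB"]])
})

test_that("linearized spectrum matches a stochastic simulation", {
  # single-draw version of the cross-module oracle (the multi-draw version
  # lives in the acceptance tests)
  sim <- simulate_timeseries(win_spec, default_params, duration = 120,
                             fs = 1000, seed = 21)
  w <- welch_psd(sim$observed, 1000, seg_len = 2000)
  i <- w$freq >= 15 & w$freq <= 35
  pred <- predict_csd(win_spec, default_params, w$freq[i],
                      condition = "LB")$spectra[, 1]
  bp_ratio <- trapz(w$freq[i], w$psd[i]) / trapz(w$freq[i], pred)
  expect_lt(abs(bp_ratio - 1), 0.15)
  expect_lt(mean(abs(w$psd[i] / pred - 1)), 0.15)
})
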