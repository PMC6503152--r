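freqs_coarse <- seq(5, 45, 1)

test_that("free energy matches an independently coded Gaussian evaluation", {
  # brute-force oracle: log-likelihood via dnorm sums plus the closed-form
  # Gaussian KL, coded independently of the package's internals
  set.seed(31)
  f <- seq(10, 40, 1)
  for (rep in 1:5) {
    n <- 2 * length(f)
    yobs <- exp(rnorm(n, 0, 1))
    ypred <- exp(log(yobs) + rnorm(n, 0, 0.1))
    dat <- csd(f, matrix(yobs, ncol = 2, dimnames = list(NULL, c("LB", "HB"))))
    prd <- csd(f, matrix(ypred, ncol = 2, dimnames = list(NULL, c("LB", "HB"))))
    d <- 5
    nm <- paste0("B", 1:d)
    m <- rnorm(d, 0, 0.2)
    A <- matrix(rnorm(d * d, 0, 0.1), d)
    Sq <- crossprod(A) + diag(0.05, d)
    h <- rnorm(1, 8, 1); vh <- runif(1, 0.01, 0.05)
    post <- list(mean = setNames(m, nm), cov = Sq, hE = c(h, vh))
    pr <- win_priors
    got <- free_energy(dat, prd, post, pr)
    # independent evaluation
    e <- log(yobs) - log(ypred)
    ll <- sum(dnorm(e, 0, exp(-h / 2), log = TRUE))
    Sp <- diag(pr$table[nm, "var"])
    kl <- 0.5 * (sum(diag(solve(Sp) %*% Sq)) +
                   t(m) %*% solve(Sp) %*% m - d +
                   log(det(Sp) / det(Sq)))
    klh <- 0.5 * (vh / (1 / 32) + (h - 12)^2 / (1 / 32) - 1 +
                    log((1 / 32) / vh))
    expect_equal(got$F, as.numeric(ll - kl - klh), tolerance = 1e-8)
    expect_equal(got$accuracy, ll, tolerance = 1e-8)
  }
})

test_that("complexity vanishes when the posterior equals the prior, and F
          reduces to the data log-normalization at zero residuals", {
  f <- seq(10, 40, 1)
  y <- matrix(exp(rnorm(62)), ncol = 2, dimnames = list(NULL, c("LB", "HB")))
  dat <- csd(f, y)
  nm <- c("G1", "G2", "B1")
  post <- list(mean = setNames(numeric(3), nm),
               cov = diag(win_priors$table[nm, "var"]),
               hE = c(12, 1 / 32))
  fe <- free_energy(dat, dat, post, win_priors)
  expect_equal(fe$complexity, 0, tolerance = 1e-12)
  expect_equal(fe$complexity_h, 0, tolerance = 1e-12)
  n <- length(y)
  expect_equal(fe$F, 0.5 * n * 12 - 0.5 * n * log(2 * pi), tolerance = 1e-10)
})

test_that("inflating residuals at a fixed posterior strictly lowers F", {
  f <- seq(10, 40, 1)
  y <- matrix(exp(rnorm(62)), ncol = 2, dimnames = list(NULL, c("LB", "HB")))
  dat <- csd(f, y)
  post <- list(mean = setNames(0.1, "B1"), cov = matrix(0.01),
               hE = c(10, 0.01))
  Fs <- sapply(c(0, 0.01, 0.05, 0.2), function(s) {
    prd <- dat; prd$spectra <- dat$spectra * exp(s)
    free_energy(dat, prd, post, win_priors)$F
  })
  expect_true(all(diff(Fs) < 0))
})

test_that("self-consistent inversion stays at the prior expectations", {
  dat <- make_dataset(win_spec, win_priors, freqs = freqs_coarse)
  fit <- quiet_fit(dat, win_spec, win_priors, free = "B")
  sds <- sqrt(win_priors$table[fit$free, "var"])
  expect_true(all(abs(coef(fit)) < 2 * sds))
  expect_true(all(abs(coef(fit)[startsWith(names(coef(fit)), "B")]) < 0.1))
})

test_that("accepted free energy is non-decreasing and the covariance stays
          positive definite", {
  dat <- make_dataset(win_spec, win_priors, pattern_theta(win_priors, 0.3),
                      freqs = freqs_coarse, noise = exp(-6), seed = 5)
  fit <- quiet_fit(dat, win_spec, win_priors, free = "B")
  Facc <- fit$trace$F[fit$trace$accepted]
  expect_true(all(diff(Facc) >= -1e-9))
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(fit$Sigma, t(fit$Sigma), tolerance = 1e-10)
})

test_that("a known condition-effect pattern is recovered", {
  th <- pattern_theta(win_priors, 0.4)
  dat <- make_dataset(win_spec, win_priors, th, freqs = freqs_coarse,
                      noise = exp(-6), seed = 17)
  fit <- quiet_fit(dat, win_spec, win_priors, free = "B")
  bn <- names(coef(fit))
  expect_gt(cor(coef(fit), th[bn]), 0.8)
  expect_identical(sign(coef(fit)), sign(th[bn]))
  # the headline modulation (MP->SP) sits inside its 90% credible interval
  b_mpsp <- win_priors$table$name[win_priors$table$label == "MP->SP" &
                                    win_priors$table$group == "B"]
  ci <- confint(fit, b_mpsp, level = 0.9)
  expect_gt(th[b_mpsp], ci[1])
  expect_lt(th[b_mpsp], ci[2])
})

test_that("fixed-precision mode holds the log-precision at its prior", {
  dat <- make_dataset(win_spec, win_priors, freqs = freqs_coarse,
                      noise = 0.05, seed = 3)
  fit <- quiet_fit(dat, win_spec, win_priors, free = "B",
                   control = betadcm_control(fixed_precision = TRUE,
                                             maxit = 16))
  expect_equal(unname(fit$hE["mean"]), 12)
  fit2 <- quiet_fit(dat, win_spec, win_priors, free = "B",
                    control = betadcm_control(maxit = 16))
  expect_lt(fit2$hE[["mean"]], 12)  # precision adapts to the noisy data
})

test_that("fit object methods are coherent", {
  dat <- make_dataset(win_spec, win_priors, pattern_theta(win_priors, 0.3),
                      freqs = freqs_coarse, noise = exp(-6), seed = 8)
  fit <- quiet_fit(dat, win_spec, win_priors, free = "B")
  expect_s3_class(fit, "betadcm")
  expect_named(coef(fit), fit$free)
  expect_equal(dim(vcov(fit)), c(length(fit$free), length(fit$free)))
  prd <- predict(fit)
  expect_s3_class(prd, "csd")
  expect_equal(prd$spectra, fit$fitted$spectra, tolerance = 1e-12)
  r <- residuals(fit)
  expect_equal(as.vector(r),
               as.vector(log(dat$spectra) - log(fitted(fit)$spectra)),
               tolerance = 1e-12)
  expect_equal(as.numeric(logLik(fit)), fit$F)
  s <- summary(fit)
  expect_s3_class(s, "summary.betadcm")
  expect_equal(s$table$estimate, unname(coef(fit)))
})

test_that("data must cover the beta band and contain the baseline", {
  dat <- make_dataset(win_spec, win_priors, freqs = seq(5, 45, 1))
  short <- csd(seq(5, 14, 1), dat$spectra[1:10, ])
  expect_error(betadcm(short, win_spec, win_priors), "15-35")
  hbonly <- csd(dat$freqs, dat$spectra[, "HB", drop = FALSE])
  colnames(hbonly$spectra) <- "HB"
  expect_error(betadcm(hbonly, win_spec, win_priors), "baseline")
})
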