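# Variational Laplace inversion of the spectral forward model.
#
# The observation model treats the log power spectra of both conditions,
# stacked, as Gaussian with iid precision exp(hE):
#     y = log S_obs,  g(theta) = log predict_csd(theta),
#     y = g(theta) + e,  e ~ N(0, exp(-hE) I).
# Residuals are taken on log-spectra to stabilize the heteroscedastic
# density scale. Free parameters have Gaussian priors N(0, v) (deviations
# from prior expectations); the data log-precision hE has prior N(12, 1/32)
# and is updated by a one-dimensional Laplace/Newton step inside each
# iteration (or held fixed, see `fixed_precision`).

# expand group shorthands ("B", "gamma_mmc", ...) into parameter names
.resolve_free <- function(priors, free) {
  tab <- priors$table
  model_names <- tab$name[tab$group != "precision"]
  if (is.null(free)) return(model_names)
  groups <- c("gamma_mmc", "gamma_tcr", "lambda", "T_mmc", "T_tcr",
              "R_mmc", "R_tcr", "noise_channel", "noise_input", "gain",
              "contribution", "B")
  out <- character(0)
  for (f in free) {
    if (f %in% groups) out <- c(out, tab$name[tab$group == f])
    else if (f %in% model_names) out <- c(out, f)
    else stop("unknown free parameter or group: ", f)
  }
  unique(out)
}

# Laplace/Newton update of the log-precision given squared residual sum S
.update_h <- function(h, S, n, h0, ph) {
  for (i in 1:12) {
    g1 <- n / 2 - 0.5 * exp(h) * S - ph * (h - h0)
    g2 <- -0.5 * exp(h) * S - ph
    step <- g1 / g2
    h <- h - step
    if (abs(step) < 1e-10) break
  }
  h
}

# free energy given residuals e, log-precision posterior (h, vh), parameter
# posterior (m, Sq) and priors (prior mean 0, covariance Sp). Laplace form
# at the posterior mean: accuracy + log-normalization - KL(q||p).
.vl_F <- function(e, h, vh, m, Sq, Sp, h0, vh0) {
  n <- length(e)
  acc <- -0.5 * exp(h) * sum(e^2) + 0.5 * n * h - 0.5 * n * log(2 * pi)
  klq <- 0
  if (length(m) > 0) {
    cp <- chol(Sp); cq <- chol(Sq)
    Pp <- chol2inv(cp)
    klq <- 0.5 * (sum(Pp * Sq) + sum(m * (Pp %*% m)) - length(m) +
                    2 * sum(log(diag(cp))) - 2 * sum(log(diag(cq))))
  }
  klh <- 0.5 * (vh / vh0 + (h - h0)^2 / vh0 - 1 + log(vh0 / vh))
  acc - klq - klh
}

#' Free energy of a model/posterior pair
#'
#' Computes the variational (Laplace) free energy -- the quantity maximized
#' during inversion and used as log model evidence -- from observed and
#' predicted spectra, a parameter posterior and the priors. Accuracy is the
#' precision-weighted squared residual on log-spectra plus the Gaussian
#' log-normalization; complexity is the Gaussian Kullback-Leibler
#' divergence between posterior and prior (parameters and log-precision).
#'
#' @param data Observed [csd()].
#' @param prediction Predicted [csd()] on the same grid and conditions.
#' @param posterior List with `mean` (named deviations from prior
#'   expectations), `cov` (their posterior covariance), and optionally `hE`
#'   (`c(mean, var)` posterior of the data log-precision; defaults to its
#'   prior).
#' @param priors A [tc_priors()].
#' @return List with `F`, `accuracy`, `complexity` (parameters) and
#'   `complexity_h` (log-precision) in nats.
#' @export
free_energy <- function(data, prediction, posterior, priors) {
  stopifnot(inherits(data, "csd"), inherits(prediction, "csd"),
            inherits(priors, "tc_priors"))
  conds <- colnames(data$spectra)
  if (!all(conds %in% colnames(prediction$spectra)))
    stop("prediction lacks a condition present in the data")
  e <- as.vector(log(data$spectra[, conds]) - log(prediction$spectra[, conds]))
  tab <- priors$table
  h0 <- tab["hE", "mean"]; vh0 <- tab["hE", "var"]
  hE <- posterior$hE
  if (is.null(hE)) hE <- c(h0, vh0)
  m <- posterior$mean
  if (length(m) > 0 && is.null(names(m))) stop("posterior mean must be named")
  Sp <- diag(tab[names(m), "var"], length(m))
  Sq <- as.matrix(posterior$cov)
  if (length(m) != nrow(Sq)) stop("posterior mean/covariance mismatch")
  ev <- eigen(Sq, symmetric = TRUE, only.values = TRUE)$values
  if (length(m) > 0 && min(ev) < -1e-8 * max(abs(ev)))
    stop("posterior covariance is not positive semi-definite")
  n <- length(e)
  acc <- -0.5 * exp(hE[1]) * sum(e^2) + 0.5 * n * hE[1] - 0.5 * n * log(2 * pi)
  Ftot <- .vl_F(e, hE[1], hE[2], m, Sq, Sp, h0, vh0)
  klh <- 0.5 * (hE[2] / vh0 + (hE[1] - h0)^2 / vh0 - 1 + log(vh0 / hE[2]))
  list(F = Ftot, accuracy = acc, complexity = acc - Ftot - klh,
       complexity_h = klh)
}

#' Control options for model inversion
#'
#' @param maxit Maximum Gauss-Newton iterations.
#' @param tol Convergence tolerance: the fit stops once the free energy has
#'   improved by less than `tol` nats over `patience` consecutive
#'   iterations.
#' @param patience Number of consecutive small-improvement iterations
#'   required to declare convergence.
#' @param fd_step Finite-difference step for the prediction Jacobian.
#' @param fixed_precision If `TRUE`, hold the data log-precision at its
#'   prior mean instead of updating it.
#' @param verbose Print the free-energy trace.
#' @return List of control options.
#' @export
betadcm_control <- function(maxit = 128L, tol = 1e-3, patience = 4L,
                            fd_step = 1e-3, fixed_precision = FALSE,
                            verbose = FALSE) {
  list(maxit = as.integer(maxit), tol = tol, patience = as.integer(patience),
       fd_step = fd_step, fixed_precision = isTRUE(fixed_precision),
       verbose = isTRUE(verbose))
}

#' Fit a thalamocortical circuit model to two-condition spectra
#'
#' Inverts the spectral forward model with a variational Laplace
#' (Gauss-Newton with step rejection) scheme: starting from the prior
#' expectations, parameters are updated to maximize the free energy bound
#' on log model evidence; steps that do not improve the bound are shrunk
#' and, failing that, rejected. Low beta is the baseline condition;
#' condition effects (B) enter only the high-beta prediction. The iterate
#' with the best free energy is returned.
#'
#' @param data A [csd()] with `LB` (and normally `HB`) columns covering at
#'   least 15--35 Hz.
#' @param model A [tc_model()].
#' @param priors A [tc_priors()] for `model`.
#' @param free Character vector of free parameter names and/or group names
#'   (`"gamma_mmc"`, `"gamma_tcr"`, `"lambda"`, `"T_mmc"`, `"T_tcr"`,
#'   `"B"`, `"gain"`, `"contribution"`, `"noise_channel"`, `"noise_input"`,
#'   `"R_mmc"`, `"R_tcr"`); `NULL` frees every model parameter.
#' @param control A [betadcm_control()] list.
#' @return An object of class `"betadcm"` with posterior mean (`mean`),
#'   covariance (`Sigma`), free-energy (`F`), fitted spectra, residuals,
#'   iteration trace and convergence flag. Standard methods (`print`,
#'   `summary`, `coef`, `vcov`, `confint`, `predict`, `residuals`,
#'   `fitted`, `plot`, `simulate`) apply.
#' @export
betadcm <- function(data, model = winning_model(),
                    priors = tc_priors(model), free = NULL,
                    control = betadcm_control()) {
  stopifnot(inherits(data, "csd"), inherits(model, "tc_model"),
            inherits(priors, "tc_priors"))
  if (min(data$freqs) > 15 || max(data$freqs) < 35)
    stop("data must cover the 15-35 Hz band")
  conds <- intersect(c("LB", "HB"), colnames(data$spectra))
  if (!"LB" %in% conds) stop("data must contain the LB baseline condition")
  freqs <- data$freqs
  y <- as.vector(log(data$spectra[, conds]))
  n <- length(y)

  fr <- .resolve_free(priors, free)
  d <- length(fr)
  tab <- priors$table
  pv <- tab[fr, "var"]
  Pp <- diag(1 / pv, d); Sp <- diag(pv, d)
  h0 <- tab["hE", "mean"]; vh0 <- tab["hE", "var"]; ph <- 1 / vh0

  fwd <- function(m) {
    th <- stats::setNames(m, fr)
    pr <- tryCatch(
      predict_csd(model, expand_params(priors, th), freqs,
                  condition = if (length(conds) == 2L) "both" else "LB"),
      error = function(e) NULL)
    if (is.null(pr)) return(NULL)
    as.vector(log(pr$spectra[, conds]))
  }

  m <- numeric(d); h <- h0
  g <- fwd(m)
  if (is.null(g))
    stop("forward model unstable or invalid at the prior expectations")
  e <- y - g
  if (any(!is.finite(e))) stop("non-finite objective at initialization",
                               " (parameter snapshot: all zeros)")
  if (!control$fixed_precision) h <- .update_h(h, sum(e^2), n, h0, ph)
  vh <- if (control$fixed_precision) vh0 else
    1 / (0.5 * exp(h) * sum(e^2) + ph)
  Sq <- Sp
  F_cur <- .vl_F(e, h, vh, m, Sq, Sp, h0, vh0)
  best <- list(m = m, h = h, vh = vh, Sq = Sq, F = F_cur, e = e)
  trace <- data.frame(iter = 0L, F = F_cur, accepted = TRUE, h = h,
                      step = 0)
  small <- 0L
  converged <- FALSE

  for (it in if (d > 0L) seq_len(control$maxit) else integer(0)) {
    # finite-difference Jacobian of the prediction at m
    J <- matrix(0, n, d)
    ok <- TRUE
    for (j in seq_len(d)) {
      dm <- m; dm[j] <- dm[j] + control$fd_step
      gp <- fwd(dm)
      if (is.null(gp)) { ok <- FALSE; break }
      J[, j] <- (gp - g) / control$fd_step
    }
    if (!ok) break
    lam <- exp(h)
    H <- lam * crossprod(J) + Pp
    Sq_new <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (is.null(Sq_new)) break
    delta <- Sq_new %*% (lam * crossprod(J, e) - Pp %*% m)
    # backtracking line search on the free energy
    accepted <- FALSE; stepsize <- 1
    for (k in 0:5) {
      m_try <- m + stepsize * as.vector(delta)
      g_try <- fwd(m_try)
      if (!is.null(g_try)) {
        e_try <- y - g_try
        h_try <- if (control$fixed_precision) h0 else
          .update_h(h, sum(e_try^2), n, h0, ph)
        vh_try <- if (control$fixed_precision) vh0 else
          1 / (0.5 * exp(h_try) * sum(e_try^2) + ph)
        F_try <- .vl_F(e_try, h_try, vh_try, m_try, Sq_new, Sp, h0, vh0)
        if (is.finite(F_try) && F_try > F_cur) {
          m <- m_try; g <- g_try; e <- e_try; h <- h_try; vh <- vh_try
          Sq <- Sq_new
          dF <- F_try - F_cur; F_cur <- F_try
          accepted <- TRUE
          break
        }
      }
      stepsize <- stepsize / 2
    }
    trace <- rbind(trace, data.frame(iter = it, F = F_cur,
                                     accepted = accepted, h = h,
                                     step = if (accepted) stepsize else 0))
    if (control$verbose)
      message(sprintf("iter %3d  F = %.4f  %s", it, F_cur,
                      if (accepted) sprintf("(step %.3g)", stepsize)
                      else "(rejected)"))
    if (F_cur > best$F) best <- list(m = m, h = h, vh = vh, Sq = Sq,
                                     F = F_cur, e = e)
    small <- if (!accepted || (accepted && (F_cur - trace$F[nrow(trace) - 1]) <
                                 control$tol)) small + 1L else 0L
    if (small >= control$patience) { converged <- TRUE; break }
  }

  theta <- stats::setNames(best$m, fr)
  fitted_csd <- predict_csd(model, expand_params(priors, theta), freqs,
                            condition = if (length(conds) == 2L) "both" else "LB")
  out <- structure(list(
    mean = theta,
    Sigma = structure(best$Sq, dimnames = list(fr, fr)),
    hE = c(mean = best$h, var = best$vh),
    F = best$F,
    free = fr,
    data = data, fitted = fitted_csd,
    residuals = matrix(best$e, ncol = length(conds),
                       dimnames = list(NULL, conds)),
    model = model, priors = priors,
    trace = trace, converged = converged,
    n_iter = max(trace$iter)
  ), class = "betadcm")
  if (!converged)
    warning("maximum iterations reached without convergence", call. = FALSE)
  out
}
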