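#' @export
print.betadcm <- function(x, ...) {
  cat("thalamocortical spectral DCM fit\n")
  print(x$model)
  cat(sprintf("  free energy: %.3f nats  (%d iterations%s)\n", x$F, x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  cat(sprintf("  %d free parameters; posterior log-precision %.2f\n",
              length(x$mean), x$hE[["mean"]]))
  invisible(x)
}

#' @export
summary.betadcm <- function(object, level = 0.9, ...) {
  ci <- confint(object, level = level)
  tab <- data.frame(
    estimate = object$mean,
    sd = sqrt(diag(object$Sigma)),
    lower = ci[, 1], upper = ci[, 2],
    label = object$priors$table[object$free, "label"]
  )
  out <- list(model = object$model, F = object$F, table = tab,
              converged = object$converged, level = level)
  class(out) <- "summary.betadcm"
  out
}

#' @export
print.summary.betadcm <- function(x, ...) {
  print(x$model)
  cat(sprintf("free energy %.3f nats; %s\n", x$F,
              if (x$converged) "converged" else "NOT converged"))
  printCoefmat(as.matrix(x$table[, 1:4]), digits = 3)
  invisible(x)
}

#' @export
coef.betadcm <- function(object, ...) object$mean

#' @export
vcov.betadcm <- function(object, ...) object$Sigma

#' @export
confint.betadcm <- function(object, parm, level = 0.95, ...) {
  sds <- sqrt(diag(object$Sigma))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$mean - z * sds, object$mean + z * sds)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  rownames(ci) <- names(object$mean)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted spectra from a fitted model
#'
#' @param object A `"betadcm"` fit.
#' @param freqs Frequency grid (defaults to the fitted grid).
#' @param condition `"both"`, `"LB"` or `"HB"`.
#' @param source Also return per-population source spectra.
#' @param ... Unused.
#' @return A [csd()].
#' @export
predict.betadcm <- function(object, freqs = NULL, condition = "both",
                            source = FALSE, ...) {
  if (is.null(freqs)) freqs <- object$data$freqs
  predict_csd(object$model, expand_params(object$priors, object$mean),
              freqs, condition = condition, source = source)
}

#' @export
residuals.betadcm <- function(object, ...) object$residuals

#' @export
fitted.betadcm <- function(object, ...) object$fitted

#' @export
logLik.betadcm <- function(object, ...) {
  structure(object$F, df = length(object$mean), class = "logLik")
}

#' @export
plot.betadcm <- function(x, ...) {
  conds <- colnames(x$data$spectra)
  cols <- c(LB = "blue", HB = "red")[conds]
  graphics::matplot(x$data$freqs, x$data$spectra, type = "p", pch = 1,
                    col = cols, log = "y", xlab = "frequency (Hz)",
                    ylab = "power spectral density", ...)
  graphics::matlines(x$fitted$freqs, x$fitted$spectra[, conds],
                     lty = 1, col = cols)
  graphics::legend("topright", bty = "n",
                   legend = c(paste(conds, "observed"),
                              paste(conds, "fitted")),
                   col = rep(cols, 2), pch = c(rep(1, length(conds)),
                                               rep(NA, length(conds))),
                   lty = c(rep(NA, length(conds)), rep(1, length(conds))))
  invisible(x)
}

#' Simulate time series from a fitted model
#'
#' Stochastic simulation of the circuit at the posterior parameter means
#' (see [simulate_timeseries()]).
#'
#' @param object A `"betadcm"` fit.
#' @param nsim Number of realizations.
#' @param seed Integer seed.
#' @param duration Seconds per realization.
#' @param fs Output sampling rate in Hz.
#' @param condition Condition to simulate.
#' @param ... Passed to [simulate_timeseries()].
#' @return A list of simulation results (invisibly a single result when
#'   `nsim = 1`).
#' @export
simulate.betadcm <- function(object, nsim = 1, seed = 1L, duration = 10,
                             fs = 1000, condition = "LB", ...) {
  p <- expand_params(object$priors, object$mean)
  out <- lapply(seq_len(nsim), function(i)
    simulate_timeseries(object$model, p, duration = duration, fs = fs,
                        seed = seed + i - 1L, condition = condition, ...))
  if (nsim == 1) out[[1]] else out
}
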