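#' Sweep condition effects and map normalized beta power
#'
#' Forward exploration of how joint changes in two condition effects shape
#' beta power: for every cell of a two-dimensional grid the two B values
#' are set, any further B values are clamped to `fixed` (others keep their
#' value in `params`), the high-beta spectrum is predicted, its 15--35 Hz
#' band power is integrated and divided by the baseline (low-beta) band
#' power. The default axes/clamp reproduce the standard exploration of the
#' strongest modulations: MP->SP and REL->DP swept with REL->RET clamped
#' weak (-1) or strong (+1).
#'
#' @param spec A [tc_model()] whose modulation includes the swept edges.
#' @param params A `"tc_params"` (baseline operating point with B entries).
#' @param axis1,axis2 Directed edge labels of the two swept condition
#'   effects (must be modulated edges of `spec`).
#' @param fixed Named list/vector clamping further modulated edges, e.g.
#'   `c("REL->RET" = -1)`.
#' @param grid Numeric grid of B values in `[-1, 1]` applied to both axes.
#' @param band Frequency band integrated (Hz).
#' @param freqs Frequency grid for spectral prediction.
#' @return An object of class `"beta_sweep"`: list with `values` (grid x
#'   grid matrix of normalized band power, axis1 on rows), `flagged`
#'   (logical matrix marking cells whose linearization was unstable;
#'   their values are `NA`), `grid`, `axes`, `fixed` and `baseline`
#'   (low-beta band power).
#' @export
#' @examples
#' \donttest{
#' p <- expand_params(tc_priors(winning_model()))
#' sw <- sweep_beta_power(winning_model(), p, grid = seq(-1, 1, by = 0.5))
#' }
sweep_beta_power <- function(spec, params, axis1 = "MP->SP",
                             axis2 = "REL->DP",
                             fixed = c("REL->RET" = -1),
                             grid = seq(-1, 1, by = 0.1),
                             band = c(15, 35),
                             freqs = seq(4, 48, by = 0.5)) {
  stopifnot(inherits(spec, "tc_model"), inherits(params, "tc_params"))
  med <- modulated_edges(spec)
  for (ax in c(axis1, axis2)) if (!ax %in% med)
    stop("axis '", ax, "' is not a modulated edge of this model")
  if (any(abs(grid) > 1)) stop("grid values must lie in [-1, 1]")
  fixed <- unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% med))
    stop("fixed edges must be modulated edges of this model")
  base <- band_power(predict_csd(spec, params, freqs, condition = "LB"),
                     band)[["LB"]]
  n <- length(grid)
  vals <- matrix(NA_real_, n, n, dimnames = list(axis1 = grid, axis2 = grid))
  flagged <- matrix(FALSE, n, n)
  p <- params
  if (length(fixed)) p$B[names(fixed)] <- fixed
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p$B[axis1] <- grid[i]
    p$B[axis2] <- grid[j]
    hb <- tryCatch(
      band_power(predict_csd(spec, p, freqs, condition = "HB"), band)[["HB"]],
      error = function(e) NA_real_)
    if (is.na(hb)) flagged[i, j] <- TRUE else vals[i, j] <- hb / base
  }
  structure(list(values = vals, flagged = flagged, grid = grid,
                 axes = c(axis1, axis2), fixed = fixed, baseline = base,
                 band = band),
            class = "beta_sweep")
}

#' @export
print.beta_sweep <- function(x, ...) {
  cat(sprintf("beta-power sweep: %s x %s (%d x %d grid), %d unstable cell(s)\n",
              x$axes[1], x$axes[2], length(x$grid), length(x$grid),
              sum(x$flagged)))
  if (length(x$fixed))
    cat("  clamped:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  cat(sprintf("  normalized band power range: %.3g .. %.3g\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.beta_sweep <- function(x, log = TRUE, ...) {
  z <- if (log) log10(x$values) else x$values
  graphics::image(x$grid, x$grid, z, xlab = paste("B on", x$axes[1]),
                  ylab = paste("B on", x$axes[2]),
                  main = if (log) "log10 normalized beta power"
                  else "normalized beta power", ...)
  invisible(x)
}

#' Per-population source spectra in both conditions
#'
#' Tabulates each population's voltage spectrum in the low- and high-beta
#' conditions (condition effects taken from `params$B`), with peak
#' frequency and beta band power per population.
#'
#' @param spec A [tc_model()].
#' @param params A `"tc_params"`.
#' @param freqs Frequency grid (Hz).
#' @param band Band integrated for the summary table.
#' @return An object of class `"population_spectra"`: list with `csd` (the
#'   observed-channel [csd()] carrying per-population `source` spectra) and
#'   `table` (population x condition peak frequency and band power).
#' @export
population_spectra <- function(spec, params, freqs = seq(4, 48, by = 0.5),
                               band = c(15, 35)) {
  x <- predict_csd(spec, params, freqs, condition = "both", source = TRUE)
  tab <- do.call(rbind, lapply(c("LB", "HB"), function(cc) {
    src <- x$source[[cc]]
    data.frame(population = .pop_names, condition = cc,
               peak_freq = freqs[apply(src, 2, which.max)],
               band_power = apply(src, 2, function(s) {
                 i <- freqs >= band[1] & freqs <= band[2]
                 f <- freqs[i]
                 sum(diff(f) * (utils::head(s[i], -1) + utils::tail(s[i], -1)) / 2)
               }), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(csd = x, table = tab, band = band),
            class = "population_spectra")
}

#' @export
print.population_spectra <- function(x, ...) {
  cat("per-population source spectra (peak frequency, band power):\n")
  print(x$table, digits = 4)
  invisible(x)
}
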