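# shared fixtures: the standard model/priors and small helpers used across
# test files. Everything is built in code; no stored data.

win_spec <- winning_model()
win_priors <- tc_priors(win_spec)
default_params <- expand_params(win_priors)

# the reported modulation sign pattern (positive on REL->II, REL->DP,
# MP->SP, REL->RET; negative elsewhere), at a given magnitude
pattern_theta <- function(priors, magnitude = 0.4) {
  th <- theta_template(priors)
  tab <- priors$table
  bn <- tab$name[tab$group == "B"]
  bl <- tab$label[tab$group == "B"]
  up <- c("MP->SP", "REL->RET", "REL->DP", "REL->II")
  th[bn] <- ifelse(bl %in% up, magnitude, -magnitude)
  th
}

# two-condition data generated by the forward model at `theta`, with iid
# log-normal observation noise of sd `noise` on the spectra
make_dataset <- function(spec, priors, theta = NULL, freqs = seq(4, 48, 0.5),
                         noise = 0, seed = 1) {
  x <- predict_csd(spec, expand_params(priors, theta), freqs, "both")
  if (noise > 0) {
    set.seed(seed)
    x$spectra <- x$spectra *
      exp(matrix(rnorm(length(x$spectra), 0, noise), nrow(x$spectra)))
  }
  x
}

quiet_fit <- function(...) suppressWarnings(betadcm(...))

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
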