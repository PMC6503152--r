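# Prior specification: every biophysical quantity is parameterized as
# prior-mean x exp(theta) (multiplicative, "log" kind) or prior-mean + theta
# (additive kind: condition effects B, noise log-amplitudes, data
# log-precision), with theta ~ Normal(0, v). Couplings are in Hz and time
# constants in milliseconds at the user surface; expand_params() converts
# time constants and delays to seconds once, internally.

# default assignment of the 14 intracortical coupling prior means to the
# canonical edge ordering (see vignette for how this permutation was chosen)
.mmc_gamma_means <- c(
  "SP->MP" = 200, "MP->SP" = 800, "SP->DP" = 400, "DP->SP" = 800,
  "SP->II" = 800, "II->SP" = 800, "MP->II" = 400, "II->MP" = 800,
  "DP->II" = 800, "II->DP" = 800, "SP->SP" = 400, "MP->MP" = 800,
  "II->II" = 400, "DP->DP" = 800
)

#' Prior expectations and variances for a thalamocortical model
#'
#' Builds the full prior specification for the baseline (low-beta)
#' condition: prior means for all circuit quantities and prior variances for
#' their free log-scaling (or additive) parameters. Defaults are the
#' package's standard operating point; the assignment of the 14
#' intracortical coupling means to directed edges is configurable because
#' it is a modelling choice (see the methods vignette).
#'
#' @param spec A [tc_model()]; determines which extrinsic connections exist
#'   and which connections carry condition effects (B parameters).
#' @param gamma_mmc Named numeric vector of 14 intracortical coupling prior
#'   means in Hz, named by directed edge in the canonical ordering.
#' @return An object of class `"tc_priors"`: a data frame-backed parameter
#'   table plus the model spec. Use [theta_template()] for the free
#'   parameter vector and [expand_params()] to obtain concrete circuit
#'   parameters.
#' @export
#' @examples
#' pr <- tc_priors(winning_model())
#' head(pr$table)
tc_priors <- function(spec = winning_model(), gamma_mmc = .mmc_gamma_means) {
  stopifnot(inherits(spec, "tc_model"))
  mmc_ids <- .edge_id(.mmc_edges[, "from"], .mmc_edges[, "to"])
  if (is.null(names(gamma_mmc))) names(gamma_mmc) <- mmc_ids
  if (!setequal(names(gamma_mmc), mmc_ids) || length(gamma_mmc) != 14L)
    stop("gamma_mmc must assign exactly the 14 canonical intracortical edges")
  gamma_mmc <- gamma_mmc[mmc_ids]
  if (any(gamma_mmc <= 0)) stop("coupling prior means must be positive")

  tg <- spec$architecture$tc_targets
  ext_ids <- c("DP->REL", "DP->RET", .edge_id("REL", tg))
  tcr_ids <- .edge_id(.tcr_edges[, "from"], .tcr_edges[, "to"])
  bed <- modulated_edges(spec)

  row <- function(name, group, mean, var, kind, label = NA_character_)
    data.frame(name = name, group = group, mean = mean, var = var,
               kind = kind, label = label, stringsAsFactors = FALSE)
  tab <- rbind(
    row(paste0("G", 1:14),  "gamma_mmc", unname(gamma_mmc), 1 / 16, "log", mmc_ids),
    row(paste0("Gt", 1:3),  "gamma_tcr", rep(800, 3), 1 / 64, "log", tcr_ids),
    row(paste0("A", seq_along(ext_ids)), "lambda", rep(800, length(ext_ids)),
        1 / 16, "log", ext_ids),
    row(paste0("T", 1:4),   "T_mmc", rep(8, 4), 1 / 16, "log",
        c("MP", "SP", "II", "DP")),
    row(paste0("Tt", 1:2),  "T_tcr", rep(8, 2), 1 / 64, "log", c("RET", "REL")),
    row("Rm", "R_mmc", 2 / 3, 1 / 32, "log"),
    row("Rt", "R_tcr", 2 / 3, 1 / 16, "log"),
    row(c("ac", "bc"), "noise_channel", c(0, 0), 1 / 128, "additive",
        c("white", "pink")),
    row(c("as", "bs"), "noise_input", c(0, 0), 1 / 128, "additive",
        c("white", "pink")),
    row("L", "gain", 1, 64, "log"),
    row(paste0("J", 1:3), "contribution", c(0.6, 0.2, 0.2), 1 / 16, "log",
        c("SP", "MP", "DP")),
    if (length(bed) > 0L)
      row(paste0("B", seq_along(bed)), "B", rep(0, length(bed)), 1 / 8,
          "additive", bed),
    row("hE", "precision", 12, 1 / 32, "additive")
  )
  rownames(tab) <- tab$name
  structure(list(spec = spec, table = tab,
                 delays = c(intrinsic = 1, extrinsic = 8)),
            class = "tc_priors")
}

#' @export
print.tc_priors <- function(x, ...) {
  cat(sprintf("priors for %d free parameters (+ fixed delays %g / %g ms)\n",
              nrow(x$table), x$delays[["intrinsic"]], x$delays[["extrinsic"]]))
  print(x$table[, c("group", "mean", "var", "kind", "label")])
  invisible(x)
}

#' Template free-parameter vector
#'
#' All free parameters are deviations from the prior expectation with prior
#' `Normal(0, v)`; the template is therefore a named zero vector.
#'
#' @param priors A [tc_priors()].
#' @return Named numeric vector of zeros.
#' @export
theta_template <- function(priors) {
  stopifnot(inherits(priors, "tc_priors"))
  stats::setNames(numeric(nrow(priors$table)), priors$table$name)
}

#' Prior precision matrix over the free parameters
#' @param priors A [tc_priors()].
#' @return Diagonal precision matrix (inverse prior variances).
#' @keywords internal
prior_precision <- function(priors) {
  diag(1 / priors$table$var, nrow(priors$table))
}

#' Expand priors and free parameters into concrete circuit parameters
#'
#' Applies the deviations `theta` to the prior means: multiplicatively
#' (`mean * exp(theta)`) for couplings, time constants, sigmoid slopes,
#' observation gain and contribution weights; additively for condition
#' effects, noise log-amplitudes and the data log-precision. Time constants
#' and delays are converted from milliseconds to seconds here.
#'
#' @param priors A [tc_priors()].
#' @param theta Named numeric vector as from [theta_template()]; entries may
#'   be a subset (missing entries default to 0).
#' @return An object of class `"tc_params"`: concrete parameter values with
#'   couplings in Hz and times in seconds.
#' @export
#' @examples
#' p <- expand_params(tc_priors(winning_model()))
#' p$T  # per-population time constants, seconds
expand_params <- function(priors, theta = NULL) {
  stopifnot(inherits(priors, "tc_priors"))
  tab <- priors$table
  th <- stats::setNames(numeric(nrow(tab)), tab$name)
  if (!is.null(theta)) {
    if (is.null(names(theta))) stop("theta must be named")
    unknown <- setdiff(names(theta), tab$name)
    if (length(unknown) > 0L)
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    th[names(theta)] <- theta
  }
  if (any(!is.finite(th))) stop("non-finite parameter deviation")
  val <- ifelse(tab$kind == "log", tab$mean * exp(th), tab$mean + th)
  names(val) <- tab$name
  pick <- function(group) {
    i <- tab$group == group
    stats::setNames(val[i], tab$label[i])
  }
  gm <- pick("gamma_mmc"); gt <- pick("gamma_tcr"); lam <- pick("lambda")
  Tm <- pick("T_mmc"); Tt <- pick("T_tcr")
  # per-population time constants in canonical order, seconds
  Tpop <- c(SP = unname(Tm["SP"]), MP = unname(Tm["MP"]), DP = unname(Tm["DP"]),
            II = unname(Tm["II"]), REL = unname(Tt["REL"]),
            RET = unname(Tt["RET"])) * 1e-3
  if (any(Tpop <= 0)) stop("non-positive time constant")
  B <- if (any(tab$group == "B")) pick("B") else stats::setNames(numeric(0), character(0))
  structure(list(
    spec = priors$spec,
    gamma_mmc = gm, gamma_tcr = gt, lambda = lam,
    T = Tpop,
    R_mmc = unname(val["Rm"]), R_tcr = unname(val["Rt"]),
    alpha_c = unname(val["ac"]), beta_c = unname(val["bc"]),
    alpha_s = unname(val["as"]), beta_s = unname(val["bs"]),
    L = unname(val["L"]), J = pick("contribution"),
    B = B, hE = unname(val["hE"]),
    d_intrinsic = priors$delays[["intrinsic"]] * 1e-3,
    D_extrinsic = priors$delays[["extrinsic"]] * 1e-3
  ), class = "tc_params")
}

#' Write / read a prior specification as a YAML config
#'
#' The config mirrors the parameter-table naming (`gamma_mmc`, `gamma_tcr`,
#' `lambda`, `T_mmc`, `T_tcr`, `B`, `R_mmc`, `R_tcr`, noise amplitudes, `L`,
#' `J`, `hE`, delays), storing prior means and variances per group; the
#' default [tc_priors()] round-trips exactly.
#'
#' @param priors A [tc_priors()].
#' @param path File path for the YAML document.
#' @return `write_priors_config` returns `path` invisibly;
#'   `read_priors_config` returns a `"tc_priors"` object.
#' @export
write_priors_config <- function(priors, path) {
  stopifnot(inherits(priors, "tc_priors"))
  tab <- priors$table
  doc <- list(
    model = list(architecture = priors$spec$architecture$id,
                 modulation = priors$spec$modulation$id),
    delays_ms = as.list(priors$delays),
    parameters = lapply(split(tab, tab$group)[unique(tab$group)], function(g)
      list(names = g$name, labels = g$label, means = g$mean,
           variances = g$var, kind = unique(g$kind)))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_priors_config
#' @export
read_priors_config <- function(path) {
  doc <- yaml::read_yaml(path)
  spec <- tc_model(doc$model$architecture, doc$model$modulation)
  pr <- tc_priors(spec)
  tab <- pr$table
  for (gname in names(doc$parameters)) {
    g <- doc$parameters[[gname]]
    i <- match(unlist(g$names), tab$name)
    if (anyNA(i)) stop("config group '", gname, "' does not match this model")
    tab$mean[i] <- as.numeric(unlist(g$means))
    tab$var[i] <- as.numeric(unlist(g$variances))
  }
  pr$table <- tab
  pr$delays <- c(intrinsic = as.numeric(doc$delays_ms$intrinsic),
                 extrinsic = as.numeric(doc$delays_ms$extrinsic))
  pr
}
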