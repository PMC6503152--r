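#' Fixed-effects Bayesian model comparison with family inference
#'
#' Sums free energies (log evidences) over subjects and normalizes the
#' exponentials into model posterior probabilities under uniform model
#' priors. Family posteriors sum member-model posteriors computed under
#' uniform *family* priors: each family receives prior mass `1/K` split
#' equally among its members, which corrects for unequal family sizes.
#'
#' @param F Numeric matrix of free energies, subjects x models (a vector is
#'   treated as one subject). Column names, if present, label the models.
#' @param families A `"family_partition"` from [model_families()], or a
#'   (possibly named) list of them; when the table has 144 columns and
#'   `families` is `NULL`, both standard partitions are used.
#' @return An object of class `"bmc"`: list with `evidence` (summed per
#'   model), `model_posteriors`, `log_bayes_factors` (relative to the best
#'   model), `family_posteriors` (one simplex per partition) and `best`
#'   (index of the winning model).
#' @export
#' @examples
#' ffx_bmc(rbind(c(0, 6), c(0, 0)), families = NULL)
ffx_bmc <- function(F, families = NULL) {
  if (is.vector(F)) F <- matrix(F, nrow = 1)
  if (!all(is.finite(F))) {
    bad <- which(!is.finite(F), arr.ind = TRUE)
    stop("missing/non-finite free energies at (subject, model): ",
         paste(sprintf("(%d, %d)", bad[, 1], bad[, 2]), collapse = ", "))
  }
  Fsum <- colSums(F)
  lse <- function(x) max(x) + log(sum(exp(x - max(x))))
  post <- exp(Fsum - lse(Fsum))
  if (is.null(families) && ncol(F) == 144L)
    families <- list(architecture = model_families("architecture"),
                     modulation = model_families("modulation"))
  if (inherits(families, "family_partition")) families <- list(families)
  fam_post <- NULL
  if (!is.null(families)) {
    fam_post <- lapply(families, function(fp) {
      stopifnot(inherits(fp, "family_partition"))
      idx <- sort(as.integer(unlist(fp$groups, use.names = FALSE)))
      if (!identical(idx, seq_len(ncol(F))))
        stop("family partition does not cover the models exactly once")
      K <- length(fp$groups)
      # uniform family priors: prior mass 1/K split within each family
      lprior <- numeric(ncol(F))
      for (g in fp$groups) lprior[g] <- -log(K) - log(length(g))
      lpost <- Fsum + lprior
      pm <- exp(lpost - lse(lpost))
      vapply(fp$groups, function(g) sum(pm[g]), numeric(1))
    })
    names(fam_post) <- names(families)
  }
  structure(list(evidence = Fsum, model_posteriors = post,
                 log_bayes_factors = Fsum - max(Fsum),
                 family_posteriors = fam_post,
                 best = which.max(Fsum)),
            class = "bmc")
}

#' @export
print.bmc <- function(x, ...) {
  cat(sprintf("fixed-effects BMC over %d models: best model %d (posterior %.4f)\n",
              length(x$evidence), x$best, x$model_posteriors[x$best]))
  for (nm in names(x$family_posteriors)) {
    fp <- x$family_posteriors[[nm]]
    cat(sprintf("  %s families: winner %s (posterior %.4f)\n",
                nm, names(fp)[which.max(fp)], max(fp)))
  }
  invisible(x)
}

#' Parametric empirical Bayes group stage
#'
#' Hierarchical Gaussian model over subject-level posteriors with a single
#' group-mean regressor: subject means are treated as noisy observations of
#' the group mean, `m_i ~ N(mu, Sigma_i + Psi)`, with diagonal
#' between-subject covariance `Psi` estimated by
#' expectation-maximization. Subjects are weighted by their posterior
#' precisions, which shrinks low-precision outliers toward the group mean.
#'
#' @param posteriors List of `"betadcm"` fits, or of lists with named `mean`
#'   and `cov` entries, all sharing the parameters in `parameters`.
#' @param parameters Character vector of parameter names taken to the group
#'   level (default: all parameters common to every subject).
#' @param maxit,tol EM iteration controls.
#' @return An object of class `"peb_group"`: `group_mean`,
#'   `group_covariance`, `between_subject_variance`, 90% credible
#'   intervals, and the subject-level means used.
#' @export
peb_group <- function(posteriors, parameters = NULL, maxit = 64L,
                      tol = 1e-8) {
  if (length(posteriors) < 2L) stop("need at least 2 subjects")
  get_mc <- function(p) {
    if (inherits(p, "betadcm")) list(mean = p$mean, cov = p$Sigma)
    else list(mean = p$mean, cov = as.matrix(p$cov))
  }
  ml <- lapply(posteriors, get_mc)
  if (is.null(parameters))
    parameters <- Reduce(intersect, lapply(ml, function(x) names(x$mean)))
  if (length(parameters) == 0L) stop("no common parameters across subjects")
  d <- length(parameters)
  ms <- lapply(ml, function(x) {
    if (!all(parameters %in% names(x$mean)))
      stop("inconsistent parameter dimensions across subjects")
    i <- match(parameters, names(x$mean))
    list(m = unname(x$mean[i]), S = unname(x$cov[i, i, drop = FALSE]))
  })
  N <- length(ms)
  M <- matrix(unlist(lapply(ms, `[[`, "m")), nrow = N,
              byrow = TRUE)                  # subjects x parameters
  mu <- colMeans(M)
  psi <- apply(M, 2, stats::var) + 1e-10
  for (it in seq_len(maxit)) {
    W <- lapply(ms, function(s) solve(s$S + diag(psi, d)))
    Wsum <- Reduce(`+`, W)
    gc_ <- solve(Wsum)
    mu_new <- as.vector(gc_ %*% Reduce(`+`, Map(function(w, s) w %*% s$m,
                                                W, ms)))
    # E-step for random effects b_i, then M-step for psi
    Psi <- diag(psi, d)
    eb2 <- matrix(0, N, d)
    for (i in seq_len(N)) {
      b <- Psi %*% W[[i]] %*% (ms[[i]]$m - mu_new)
      Vb <- Psi - Psi %*% W[[i]] %*% Psi
      eb2[i, ] <- as.vector(b)^2 + diag(Vb)
    }
    psi_new <- pmax(colMeans(eb2), 1e-12)
    conv <- max(abs(mu_new - mu)) + max(abs(psi_new - psi))
    mu <- mu_new; psi <- psi_new
    if (conv < tol) break
  }
  W <- lapply(ms, function(s) solve(s$S + diag(psi, d)))
  gcov <- solve(Reduce(`+`, W))
  z <- stats::qnorm(0.95)
  ci <- cbind(lower = mu - z * sqrt(diag(gcov)),
              upper = mu + z * sqrt(diag(gcov)))
  structure(list(group_mean = stats::setNames(mu, parameters),
                 group_covariance = structure(gcov,
                                              dimnames = list(parameters, parameters)),
                 between_subject_variance = stats::setNames(psi, parameters),
                 ci90 = ci, parameters = parameters, n_subjects = N,
                 subject_means = M),
            class = "peb_group")
}

#' @export
print.peb_group <- function(x, ...) {
  cat(sprintf("PEB group stage: %d subjects, %d parameters\n",
              x$n_subjects, length(x$parameters)))
  print(round(data.frame(mean = x$group_mean,
                         sd = sqrt(diag(x$group_covariance)),
                         between_sd = sqrt(x$between_subject_variance)), 4))
  invisible(x)
}

#' Condition-effect report: signed modulation of each connection
#'
#' Converts group-level condition-effect estimates (B parameters) into a
#' signed modulation table: the low-to-high-beta change per connection,
#' together with the absolute low-beta and high-beta coupling strengths
#' (prior mean times the exponential of the relevant group estimates).
#' Negative changes indicate a reduction in connectivity strength, positive
#' an increase.
#'
#' @param group A `"peb_group"` computed over (at least) B parameters.
#' @param priors The [tc_priors()] shared by the subjects.
#' @return Data frame with one row per modulated connection: `connection`,
#'   `B` (group log-scaling change), `sd`, `sign`, `coupling_LB`,
#'   `coupling_HB` (Hz).
#' @export
condition_effects <- function(group, priors) {
  stopifnot(inherits(group, "peb_group"), inherits(priors, "tc_priors"))
  tab <- priors$table
  bnames <- intersect(group$parameters, tab$name[tab$group == "B"])
  if (length(bnames) == 0L) stop("group result contains no B parameters")
  out <- do.call(rbind, lapply(bnames, function(bn) {
    edge <- tab[bn, "label"]
    B <- group$group_mean[[bn]]
    # baseline coupling: prior mean, rescaled by the group estimate of the
    # matching coupling log-scaling when that parameter is in the group set
    crow <- tab[tab$label == edge & tab$group %in%
                  c("gamma_mmc", "gamma_tcr", "lambda"), , drop = FALSE]
    lb <- crow$mean[1]
    if (crow$name[1] %in% group$parameters)
      lb <- lb * exp(group$group_mean[[crow$name[1]]])
    data.frame(connection = edge, B = B,
               sd = sqrt(group$group_covariance[bn, bn]),
               sign = sign(B), coupling_LB = lb,
               coupling_HB = lb * exp(B), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
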