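#' Neural populations of the thalamocortical circuit
#'
#' The circuit comprises six averaged neural populations: four in motor
#' cortex -- superficial (SP), middle (MP) and deep (DP) pyramidal cells and
#' a common pool of inhibitory interneurons (II) -- and two in thalamus --
#' excitatory relay cells (REL) and inhibitory reticular cells (RET).
#'
#' @return A data frame with columns `name`, `polarity`
#'   (`"excitatory"`/`"inhibitory"`) and `structure` (`"cortex"`/`"thalamus"`),
#'   one row per population, in the canonical state ordering
#'   SP, MP, DP, II, REL, RET.
#' @export
#' @examples
#' tc_populations()
tc_populations <- function() {
  data.frame(
    name      = c("SP", "MP", "DP", "II", "REL", "RET"),
    polarity  = c("excitatory", "excitatory", "excitatory", "inhibitory",
                  "excitatory", "inhibitory"),
    structure = c("cortex", "cortex", "cortex", "cortex",
                  "thalamus", "thalamus"),
    stringsAsFactors = FALSE
  )
}

# canonical population order used for all matrices and state vectors
.pop_names <- c("SP", "MP", "DP", "II", "REL", "RET")

# the nine candidate sets of laminar targets of thalamocortical afferents
.arch_targets <- list(
  "1" = "SP",
  "2" = "MP",
  "3" = "DP",
  "4" = c("SP", "MP"),
  "5" = c("MP", "DP"),
  "6" = c("SP", "DP"),
  "7" = c("SP", "II"),
  "8" = c("MP", "II"),
  "9" = c("DP", "II")
)

# canonical ordering of the 14 directed intracortical edges
.mmc_edges <- matrix(c(
  "SP", "MP",
  "MP", "SP",
  "SP", "DP",
  "DP", "SP",
  "SP", "II",
  "II", "SP",
  "MP", "II",
  "II", "MP",
  "DP", "II",
  "II", "DP",
  "SP", "SP",
  "MP", "MP",
  "II", "II",
  "DP", "DP"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("from", "to")))

# the three intrathalamic edges
.tcr_edges <- matrix(c(
  "REL", "RET",
  "RET", "REL",
  "RET", "RET"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("from", "to")))

.edge_id <- function(from, to) paste0(from, "->", to)

# intrinsic modulatory motifs indexed by the modulation-config scheme
.mod_motifs <- list(
  c("SP->DP", "DP->SP"),
  c("SP->MP", "MP->SP"),
  c("II->II"),
  c("REL->RET", "RET->REL"),
  c("SP->DP", "DP->SP", "REL->RET", "RET->REL"),
  c("SP->MP", "MP->SP", "REL->RET", "RET->REL"),
  c("II->II", "REL->RET", "RET->REL")
)

#' Thalamocortical wiring architecture
#'
#' The nine candidate architectures share all intracortical, intrathalamic
#' and corticothalamic (DP to REL, DP to RET) connections and differ only in
#' the laminar targets of thalamocortical afferents from relay cells.
#'
#' @param id Integer 1--9. Targets are, in order: \{SP\}, \{MP\}, \{DP\},
#'   \{SP,MP\}, \{MP,DP\}, \{SP,DP\}, \{SP,II\}, \{MP,II\}, \{DP,II\}.
#' @return An object of class `"tc_architecture"` with fields `id` and
#'   `tc_targets`.
#' @export
#' @examples
#' tc_architecture(9)$tc_targets  # DP and II
tc_architecture <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 9L)
    stop("architecture id must be a single integer in 1..9")
  structure(list(id = id, tc_targets = .arch_targets[[as.character(id)]]),
            class = "tc_architecture")
}

#' Condition-modulation configuration
#'
#' Each configuration names the set of directed connections that carry
#' condition-specific effects (B parameters) transforming the low-beta
#' baseline circuit into the high-beta circuit. Configurations 1--7 combine
#' one intrinsic motif with all extrinsic (corticothalamic plus
#' thalamocortical) connections; 8 modulates the extrinsic connections only;
#' 9--15 are the intrinsic motifs alone; 16 modulates nothing (the null
#' configuration). The intrinsic motifs are, in order: SP-DP reciprocal,
#' SP-MP reciprocal, II self, REL-RET reciprocal, SP-DP + REL-RET,
#' SP-MP + REL-RET, II self + REL-RET.
#'
#' @param id Integer 1--16.
#' @return An object of class `"tc_modulation"` with fields `id`,
#'   `intrinsic` (character vector of directed edge labels) and `extrinsic`
#'   (logical: are extrinsic connections modulated?).
#' @export
#' @examples
#' tc_modulation(6)   # SP-MP + REL-RET motif plus extrinsic connections
#' tc_modulation(16)  # null configuration
tc_modulation <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 16L)
    stop("modulation id must be a single integer in 1..16")
  if (id <= 7L) {
    intr <- .mod_motifs[[id]]; extr <- TRUE
  } else if (id == 8L) {
    intr <- character(0); extr <- TRUE
  } else if (id <= 15L) {
    intr <- .mod_motifs[[id - 8L]]; extr <- FALSE
  } else {
    intr <- character(0); extr <- FALSE
  }
  structure(list(id = id, intrinsic = intr, extrinsic = extr),
            class = "tc_modulation")
}

#' Specify one candidate thalamocortical circuit model
#'
#' Combines a wiring architecture (which cortical populations receive
#' thalamocortical afferents) with a modulation configuration (which
#' connections carry condition-specific effects).
#'
#' @param architecture A [tc_architecture()] or an integer 1--9.
#' @param modulation A [tc_modulation()] or an integer 1--16.
#' @return An object of class `"tc_model"` with fields `architecture` and
#'   `modulation`.
#' @export
#' @examples
#' m <- tc_model(9, 6)
#' modulated_edges(m)
tc_model <- function(architecture, modulation) {
  if (!inherits(architecture, "tc_architecture"))
    architecture <- tc_architecture(architecture)
  if (!inherits(modulation, "tc_modulation"))
    modulation <- tc_modulation(modulation)
  spec <- structure(list(architecture = architecture, modulation = modulation),
                    class = "tc_model")
  # every modulated edge must exist in this architecture
  ex <- .edge_id(.spec_edges(spec)$from, .spec_edges(spec)$to)
  bad <- setdiff(modulated_edges(spec), ex)
  if (length(bad) > 0L)
    stop("modulated connection(s) absent from the architecture: ",
         paste(bad, collapse = ", "))
  spec
}

#' @export
print.tc_model <- function(x, ...) {
  cat(sprintf("thalamocortical model: architecture %d (REL -> %s), modulation %d\n",
              x$architecture$id,
              paste(x$architecture$tc_targets, collapse = ","),
              x$modulation$id))
  me <- modulated_edges(x)
  cat(sprintf("  modulated connections (%d): %s\n", length(me),
              if (length(me)) paste(me, collapse = ", ") else "none"))
  invisible(x)
}

# full directed-edge table of a model: from, to, type, delay class
.spec_edges <- function(spec) {
  tg <- spec$architecture$tc_targets
  from <- c(.mmc_edges[, "from"], .tcr_edges[, "from"],
            "DP", "DP", rep("REL", length(tg)))
  to   <- c(.mmc_edges[, "to"], .tcr_edges[, "to"],
            "REL", "RET", tg)
  type <- c(rep("mmc", 14L), rep("tcr", 3L),
            rep("extrinsic", 2L + length(tg)))
  data.frame(from = from, to = to, type = type, stringsAsFactors = FALSE)
}

#' Directed connections carrying condition-specific effects
#'
#' Resolves a model's modulation configuration into the concrete set of
#' directed connections that are rescaled by `exp(B)` in the high-beta
#' condition, in the documented B ordering: intrinsic cortical edges first
#' (canonical edge order), then intrinsic thalamic edges, then extrinsic
#' edges (DP->REL, DP->RET, REL->target1, REL->target2).
#'
#' @param spec A [tc_model()].
#' @return Character vector of directed edge labels such as `"MP->SP"`.
#' @export
modulated_edges <- function(spec) {
  stopifnot(inherits(spec, "tc_model"))
  intr <- spec$modulation$intrinsic
  mmc_ids <- .edge_id(.mmc_edges[, "from"], .mmc_edges[, "to"])
  tcr_ids <- .edge_id(.tcr_edges[, "from"], .tcr_edges[, "to"])
  out <- c(mmc_ids[mmc_ids %in% intr], tcr_ids[tcr_ids %in% intr])
  if (spec$modulation$extrinsic) {
    tg <- spec$architecture$tc_targets
    out <- c(out, "DP->REL", "DP->RET", .edge_id("REL", tg))
  }
  out
}

#' Enumerate the factorial model space
#'
#' All 144 candidate models: 9 architectures crossed with 16 modulation
#' configurations, ordered architecture-major (models 1--16 share
#' architecture 1, and so on). The ordering is fixed so that result tables
#' are comparable across runs.
#'
#' @return A list of 144 [tc_model()] objects.
#' @export
#' @examples
#' length(enumerate_models())
enumerate_models <- function() {
  out <- vector("list", 144L)
  k <- 0L
  for (a in 1:9) for (m in 1:16) {
    k <- k + 1L
    out[[k]] <- tc_model(a, m)
  }
  out
}

#' Family partition of the model space
#'
#' Groups the 144 models into families by one design factor: 9 families of
#' 16 models when partitioning by architecture, or 16 families of 9 models
#' when partitioning by modulation configuration.
#'
#' @param factor `"architecture"` or `"modulation"`.
#' @return An object of class `"family_partition"`: a list with `factor` and
#'   `groups`, a named list mapping family id to model indices in the
#'   [enumerate_models()] ordering.
#' @export
#' @examples
#' lengths(model_families("architecture")$groups)
model_families <- function(factor = c("architecture", "modulation")) {
  factor <- match.arg(factor)
  idx <- seq_len(144L)
  arch <- (idx - 1L) %/% 16L + 1L
  modc <- (idx - 1L) %% 16L + 1L
  key <- if (factor == "architecture") arch else modc
  groups <- split(idx, key)
  names(groups) <- as.character(sort(unique(key)))
  structure(list(factor = factor, groups = groups),
            class = "family_partition")
}

#' The model with highest evidence in the original analysis
#'
#' Architecture 9 (thalamocortical afferents to deep pyramidal cells and
#' inhibitory interneurons) with modulation configuration 6 (condition
#' effects on the SP-MP and REL-RET reciprocal connections plus all four
#' extrinsic connections), giving eight modulated directed connections.
#'
#' @return A [tc_model()].
#' @export
#' @examples
#' winning_model()
winning_model <- function() tc_model(9L, 6L)
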