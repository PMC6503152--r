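#' Centered sigmoid firing-rate function
#'
#' Converts an averaged membrane potential into a (dimensionless) firing
#' rate via the centered logistic `S(v) = 1/(1 + exp(-R v)) - 1/2`, bounded
#' in (-0.5, 0.5), odd, and strictly increasing for `R > 0`. Centering makes
#' the origin an exact fixed point of the circuit at zero input.
#'
#' @param v Membrane potential (arbitrary units); any numeric array.
#' @param R Sigmoid slope, `R > 0`.
#' @return Firing rate, same shape as `v`.
#' @export
#' @examples
#' sigmoid_rate(0, 2/3)      # 0
#' sigmoid_rate(1e3, 2/3)    # -> 0.5
sigmoid_rate <- function(v, R) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  if (any(R <= 0)) stop("sigmoid slope R must be positive")
  1 / (1 + exp(-R * v)) - 0.5
}

# derivative of the centered sigmoid
.sigmoid_slope <- function(v, R) {
  s <- 1 / (1 + exp(-R * v))
  R * s * (1 - s)
}

#' Signed coupling, delay and input-map matrices of a circuit
#'
#' Assembles the 6x6 population-level connectivity of a model: intracortical
#' edges (five reciprocal pairs plus four self-connections), intrathalamic
#' edges (REL-RET reciprocal plus RET self), corticothalamic projections
#' (DP to REL and RET) and the architecture's thalamocortical afferents.
#' Edges originating at an inhibitory population (II, RET) and all
#' self-connections are negative (GABAergic); all other edges are positive
#' (glutamatergic). Delays are 1 ms within a structure and 8 ms between
#' structures. Exogenous input drives MP and REL.
#'
#' In the high-beta condition the modulated edges are rescaled by `exp(B)`.
#'
#' @param spec A [tc_model()].
#' @param params A `"tc_params"` from [expand_params()].
#' @param condition `"LB"` (baseline) or `"HB"` (condition effects applied).
#' @return List with `C` (6x6 signed couplings in Hz, rows = target),
#'   `D` (6x6 delays in seconds, zero where no edge), and `input`
#'   (length-6 0/1 vector marking driven populations).
#' @export
#' @examples
#' bc <- build_connectivity(winning_model(), expand_params(tc_priors()))
#' bc$C["RET", "RET"] < 0
build_connectivity <- function(spec, params, condition = c("LB", "HB")) {
  stopifnot(inherits(spec, "tc_model"), inherits(params, "tc_params"))
  condition <- match.arg(condition)
  pops <- .pop_names
  C <- matrix(0, 6, 6, dimnames = list(pops, pops))
  D <- matrix(0, 6, 6, dimnames = list(pops, pops))
  inhib <- c("II", "RET")
  add_edge <- function(from, to, g, delay) {
    s <- if (from %in% inhib || from == to) -1 else 1
    C[to, from] <<- C[to, from] + s * g
    D[to, from] <<- delay
  }
  for (i in seq_len(nrow(.mmc_edges)))
    add_edge(.mmc_edges[i, "from"], .mmc_edges[i, "to"],
             params$gamma_mmc[[i]], params$d_intrinsic)
  for (i in seq_len(nrow(.tcr_edges)))
    add_edge(.tcr_edges[i, "from"], .tcr_edges[i, "to"],
             params$gamma_tcr[[i]], params$d_intrinsic)
  lam <- params$lambda
  for (nm in names(lam)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    add_edge(ft[1], ft[2], lam[[nm]], params$D_extrinsic)
  }
  if (condition == "HB" && length(params$B) > 0L) {
    miss <- setdiff(names(params$B), .edge_id(
      .spec_edges(spec)$from, .spec_edges(spec)$to))
    if (length(miss) > 0L)
      stop("modulated connection(s) absent from the architecture: ",
           paste(miss, collapse = ", "))
    for (nm in names(params$B)) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      C[ft[2], ft[1]] <- C[ft[2], ft[1]] * exp(params$B[[nm]])
    }
  }
  input <- stats::setNames(as.numeric(pops %in% c("MP", "REL")), pops)
  list(C = C, D = D, input = input)
}

#' Time derivative of the circuit state
#'
#' Implements the second-order synaptic convolution dynamics per population:
#' `vdotdot_j = (sum_k C_jk S(v_k) + I_j - 2 vdot_j - v_j / T_j) / T_j`,
#' with the sigmoid slope chosen per structure (cortex / thalamus). Delayed
#' presynaptic potentials are the caller's responsibility: pass them via
#' `state_delayed` (defaults to `state`, i.e. the delay-free system used
#' for fixed points and Jacobians).
#'
#' @param state Numeric state vector of length 12, ordered
#'   `(v_SP..v_RET, vdot_SP..vdot_RET)`.
#' @param input Exogenous drive: scalar or length-6 vector added to the
#'   driven populations' synaptic input (the input map of
#'   [build_connectivity()] selects MP and REL when a scalar is given).
#' @param params A `"tc_params"`.
#' @param spec A [tc_model()].
#' @param condition Condition whose couplings to use.
#' @param state_delayed Optional 6x6 matrix of delayed presynaptic
#'   potentials, entry `[j, k]` being `v_k(t - D_jk)`; defaults to the
#'   current potentials.
#' @param conn Optionally a precomputed [build_connectivity()] result.
#' @return Numeric length-12 derivative of `state`.
#' @export
#' @examples
#' p <- expand_params(tc_priors())
#' dynamics(rep(0, 12), 0, p, winning_model())  # origin is a fixed point
dynamics <- function(state, input, params, spec, condition = "LB",
                     state_delayed = NULL, conn = NULL) {
  if (length(state) != 12L || any(!is.finite(state)))
    stop("state must be a finite vector of length 12")
  if (any(params$T <= 0)) stop("non-positive time constant")
  if (is.null(conn)) conn <- build_connectivity(spec, params, condition)
  v <- state[1:6]; vdot <- state[7:12]
  R <- c(rep(params$R_mmc, 4), rep(params$R_tcr, 2))
  if (is.null(state_delayed)) {
    drive <- as.vector(conn$C %*% sigmoid_rate(v, R))
  } else {
    stopifnot(identical(dim(state_delayed), c(6L, 6L)))
    Sm <- sigmoid_rate(state_delayed, matrix(R, 6, 6, byrow = TRUE))
    drive <- rowSums(conn$C * Sm)
  }
  I <- if (length(input) == 1L) conn$input * input else as.numeric(input)
  vddot <- (drive + I - 2 * vdot - v / params$T) / params$T
  unname(c(vdot, vddot))
}
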