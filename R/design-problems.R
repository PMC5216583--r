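# ---------------------------------------------------------------------------
# Building-block objectives and constraints, target trains, echo weighting,
# and piecewise-constant parameter grouping.
# ---------------------------------------------------------------------------

#' Specify a sequence-design problem
#'
#' Bundles the objective selector, target echo train, per-echo weights,
#' constraint list and tissue/timing parameters of one design problem.
#'
#' @param objective one of `"error_to_target"` (weighted squared error to a
#'   target echo train), `"maximize_signal"` (negative weighted echo energy)
#'   or `"total_power"` (half the sum of squared amplitudes).
#' @param N train length (excitation plus N-1 refocusing pulses).
#' @param tissue a [tissue_params()] object.
#' @param K maximum configuration order; default `min(N, 25)`.
#' @param target complex echo target of length N-1 (only the echo component
#'   is specified; all other state components are implicitly zero). Required
#'   by the error objective and the target-error constraint.
#' @param weights non-negative per-echo weights `c_n`, length N-1
#'   (default all 1).
#' @param constraints list of constraint specifications, each a list with a
#'   `type` field:
#'   * `list(type = "peak_amplitude", alpha_max = <deg>,
#'     include_excitation = TRUE)` — per-pulse bound `alpha_j <= alpha_max`
#'     (standard mode) or per-pulse-per-channel
#'     `x^2 + y^2 <= alpha_max^2` (pTx mode);
#'   * `list(type = "total_power", power_max = <rad^2>)` — total RF power
#'     bound;
#'   * `list(type = "target_error", sigma = <scalar>)` — weighted squared
#'     error to `target` bounded by `sigma^2`.
#' @param fields a `transmit_field_set` for pTx problems, or `NULL` for
#'   standard single-channel problems.
#' @return an object of class `design_problem`.
#' @export
design_problem <- function(objective = c("error_to_target", "maximize_signal",
                                         "total_power"),
                           N, tissue, K = NULL, target = NULL,
                           weights = NULL, constraints = list(),
                           fields = NULL) {
  objective <- match.arg(objective)
  if (N < 2) stop("N must be at least 2")
  if (is.null(K)) K <- default_K(N)
  if (is.null(weights)) weights <- rep(1, N - 1)
  if (length(weights) != N - 1) stop("weights must have length N - 1")
  if (any(weights < 0)) stop("negative echo weights are not allowed")
  if (!is.null(target) && length(target) != N - 1)
    stop("target must have length N - 1")
  if (objective == "error_to_target" && is.null(target))
    stop("the error objective needs a target echo train")
  for (cs in constraints) {
    if (is.null(cs$type) ||
        !cs$type %in% c("peak_amplitude", "total_power", "target_error"))
      stop("unknown constraint type: ", cs$type)
    if (cs$type == "peak_amplitude" && (is.null(cs$alpha_max) || cs$alpha_max <= 0))
      stop("peak_amplitude constraint needs alpha_max > 0")
    if (cs$type == "total_power" && (is.null(cs$power_max) || cs$power_max <= 0))
      stop("total_power constraint needs power_max > 0")
    if (cs$type == "target_error") {
      if (is.null(cs$sigma) || cs$sigma <= 0)
        stop("target_error constraint needs sigma > 0")
      if (is.null(target)) stop("target_error constraint needs a target")
    }
  }
  structure(list(objective = objective, N = as.integer(N), K = as.integer(K),
                 tissue = tissue, target = if (is.null(target)) NULL else
                   as.complex(target),
                 weights = as.numeric(weights), constraints = constraints,
                 fields = fields,
                 mode = if (is.null(fields)) "standard" else "ptx"),
            class = "design_problem")
}

#' Weighted squared-error objective
#'
#' `0.5 * sum_r sum_n c_n |s_{n,r} - t_n|^2` over echoes (and voxels in pTx
#' mode, where `echoes` is a matrix with one column per voxel).
#'
#' @param echoes complex echo train (length N-1) or matrix (N-1 x R).
#' @param target complex target train, length N-1.
#' @param weights non-negative per-echo weights, length N-1.
#' @return scalar objective value.
#' @export
error_objective <- function(echoes, target, weights = NULL) {
  echoes <- as.matrix(echoes)
  if (is.null(weights)) weights <- rep(1, nrow(echoes))
  if (any(weights < 0)) stop("negative echo weights are not allowed")
  if (length(target) != nrow(echoes) || length(weights) != nrow(echoes))
    stop("echoes, target and weights must agree in length")
  0.5 * sum(weights * rowSums(Mod(echoes - target)^2))
}

#' Signal-amplitude objective (to be minimized)
#'
#' `-0.5 * sum_r sum_n c_n |s_{n,r}|^2`; minimizing it maximizes the
#' weighted echo energy. Zero weights mask echoes (e.g. `c_n = 0` for the
#' first M echoes removes them from the objective).
#'
#' @inheritParams error_objective
#' @return scalar objective value (non-positive).
#' @export
signal_objective <- function(echoes, weights = NULL) {
  echoes <- as.matrix(echoes)
  if (is.null(weights)) weights <- rep(1, nrow(echoes))
  if (length(weights) != nrow(echoes))
    stop("echoes and weights must agree in length")
  -0.5 * sum(weights * rowSums(Mod(echoes)^2))
}

#' Total RF power
#'
#' `0.5 * sum_n alpha_n^2` for a standard train, or
#' `0.5 * sum_n sum_l (x_{n,l}^2 + y_{n,l}^2)` for a pTx channel drive.
#' Used both as an objective and as the value side of a total-power
#' constraint.
#'
#' @param x a [pulse_train()] or a `channel_drive`.
#' @return scalar power in nominal rad^2.
#' @export
total_power <- function(x) {
  if (inherits(x, "pulse_train")) return(0.5 * sum(x$alpha^2))
  if (inherits(x, "channel_drive")) return(0.5 * sum(x$x^2 + x$y^2))
  stop("total_power expects a pulse_train or channel_drive")
}

#' Peak-amplitude constraint values
#'
#' Standard mode: `alpha_j - alpha_max` per pulse. pTx mode:
#' `x_{n,l}^2 + y_{n,l}^2 - alpha_max^2` per pulse and channel. The design
#' is feasible iff all values are `<= 0`.
#'
#' @param x a [pulse_train()] or a `channel_drive`.
#' @param alpha_max peak nominal amplitude bound, radians.
#' @param include_excitation if `FALSE`, the first pulse is excluded
#'   (standard mode only).
#' @return numeric vector of constraint values.
#' @export
peak_constraints <- function(x, alpha_max, include_excitation = TRUE) {
  if (inherits(x, "pulse_train")) {
    a <- if (include_excitation) x$alpha else x$alpha[-1]
    return(a - alpha_max)
  }
  if (inherits(x, "channel_drive"))
    return(as.vector(x$x^2 + x$y^2) - alpha_max^2)
  stop("peak_constraints expects a pulse_train or channel_drive")
}

# ---------------------------------------------------------------------------
# Piecewise-constant parameter grouping
# ---------------------------------------------------------------------------

#' Build a piecewise-constant grouping scheme
#'
#' Constrains `(alpha_n, phi_n)` to be constant on each index group:
#' `alpha = Q a`, `phi = Q b` with `Q` the N x G binary incidence matrix of
#' an ordered partition of the pulse indices. Gradients project back by the
#' chain rule, `ds/da = (ds/dalpha) Q`.
#'
#' @param groups list of integer vectors (1-based pulse indices, pulse 1
#'   being the excitation) forming an ordered partition of `1..N`.
#' @param N train length.
#' @return an object of class `grouping_scheme` with fields `groups`,
#'   `index` (length-N group id per pulse), `Q` (N x G incidence matrix)
#'   and `G`.
#' @export
#' @examples
#' # 7 pulses reduced to 4 amplitude (and 4 phase) parameters:
#' build_grouping(list(1, 2, 3:5, 6:7), N = 7)
build_grouping <- function(groups, N) {
  groups <- lapply(groups, function(g) as.integer(sort(g)))
  idx <- unlist(groups)
  if (length(idx) != N || anyDuplicated(idx) || !setequal(idx, seq_len(N)))
    stop("groups must form a partition of 1..N")
  index <- integer(N)
  for (j in seq_along(groups)) index[groups[[j]]] <- j
  G <- length(groups)
  Q <- matrix(0L, nrow = N, ncol = G)
  Q[cbind(seq_len(N), index)] <- 1L
  structure(list(groups = groups, index = index, Q = Q, G = G, N = N),
            class = "grouping_scheme")
}

#' Singleton grouping (every pulse its own parameter)
#'
#' @param N train length.
#' @return a `grouping_scheme` whose incidence matrix is the identity.
#' @export
singleton_grouping <- function(N) build_grouping(as.list(seq_len(N)), N)

#' Expand grouped values to per-pulse values
#'
#' @param scheme a [build_grouping()] scheme.
#' @param a grouped values, length G.
#' @return per-pulse values, length N (`Q %*% a`).
#' @export
expand_grouped <- function(scheme, a) {
  if (length(a) != scheme$G) stop("grouped vector has wrong length")
  a[scheme$index]
}

#' Project a per-pulse gradient onto grouped variables
#'
#' Chain rule for `alpha = Q a`: `ds/da = (ds/dalpha) Q`, i.e. the per-pulse
#' gradient entries of each group are summed.
#'
#' @param scheme a [build_grouping()] scheme.
#' @param g per-pulse gradient, length N.
#' @return grouped gradient, length G.
#' @export
project_gradient <- function(scheme, g) {
  if (length(g) != scheme$N) stop("gradient has wrong length")
  as.numeric(rowsum(as.numeric(g), scheme$index, reorder = TRUE))
}

#' Count real design parameters of a grouping scheme
#'
#' `2 G` for a standard (single-channel) design — one amplitude and one
#' phase per group — or `2 G L` for an L-channel pTx design, where each
#' group carries a real and imaginary weight per channel.
#'
#' @param scheme a [build_grouping()] scheme.
#' @param L number of transmit channels (pTx mode).
#' @param ptx if `TRUE`, count pTx parameters.
#' @return integer parameter count.
#' @export
count_design_parameters <- function(scheme, L = 1L, ptx = FALSE) {
  if (ptx) 2L * scheme$G * as.integer(L) else 2L * scheme$G
}

# ---------------------------------------------------------------------------
# Objective / constraint evaluation on trains and drives
# ---------------------------------------------------------------------------

# internal: echoes for either mode. Returns matrix (N-1) x R (R = 1 standard).
problem_echoes <- function(problem, x) {
  if (problem$mode == "standard") {
    traj <- forward_simulate(x, problem$tissue, problem$K)
    matrix(echo_amplitudes(traj), ncol = 1)
  } else {
    spatial_echoes(x, problem$fields, problem$tissue, problem$K)
  }
}

#' Evaluate the objective of a design problem
#'
#' @param problem a [design_problem()].
#' @param x a [pulse_train()] (standard mode) or `channel_drive` (pTx mode).
#' @return scalar objective value.
#' @export
evaluate_objective <- function(problem, x) {
  switch(problem$objective,
    total_power = total_power(x),
    error_to_target = error_objective(problem_echoes(problem, x),
                                      problem$target, problem$weights),
    maximize_signal = signal_objective(problem_echoes(problem, x),
                                       problem$weights))
}

#' Evaluate all constraint values of a design problem
#'
#' @inheritParams evaluate_objective
#' @return named list of numeric constraint-value vectors (feasible iff all
#'   entries `<= 0`); empty list if the problem is unconstrained.
#' @export
evaluate_constraints <- function(problem, x) {
  out <- list()
  for (i in seq_along(problem$constraints)) {
    cs <- problem$constraints[[i]]
    val <- switch(cs$type,
      peak_amplitude = peak_constraints(
        x, cs$alpha_max,
        include_excitation = !isFALSE(cs$include_excitation)),
      total_power = total_power(x) - cs$power_max,
      target_error = error_objective(problem_echoes(problem, x),
                                     problem$target, problem$weights) -
        cs$sigma^2)
    out[[paste0(cs$type, "_", i)]] <- val
  }
  out
}

#' Target echo train from the ideal EPG response of a reference train
#'
#' Simulates a reference flip-angle train under a homogeneous (B = 1)
#' transmit field and returns its complex echo train, to be used as the
#' target `t_n` of an error objective ("the EPG response of a printed
#' reference train defines the target").
#'
#' @param alpha reference amplitudes in degrees.
#' @param phi reference phases in degrees; default CPMG.
#' @param tissue a [tissue_params()].
#' @param K maximum configuration order.
#' @return complex echo train of length `length(alpha) - 1`.
#' @export
epg_of_train <- function(alpha, phi = NULL, tissue, K = NULL) {
  if (is.null(phi)) phi <- cpmg_phases(length(alpha))
  tr <- pulse_train(alpha, phi, units = "degrees")
  echo_amplitudes(forward_simulate(tr, tissue, K))
}
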