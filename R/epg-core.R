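#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# EPG core: configuration states, operators, forward simulation.
#
# A configuration state of maximum order K is stored as a 3 x (K+1) complex
# matrix `mat`: row 1 = F_k^+, row 2 = F_k^-, row 3 = Z_k, column j holding
# order k = j - 1.  Flattening `mat` column-major gives the canonical state
# vector ordering (F0+, F0-, Z0, F1+, F1-, Z1, ..., FK+, FK-, ZK).
#
# Storage convention: F_k^+ holds the transverse Fourier coefficient of
# order +k and F_k^- holds the coefficient of order -k of the conjugate
# transverse component, so that F_0^+ = conj(F_0^-) for any state reachable
# from equilibrium.
# ---------------------------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval \[-180, 180).
#' @export
wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Tissue and timing parameters
#'
#' Bundles the longitudinal and transverse relaxation times and the echo
#' spacing used by the relaxation operator. With `relaxation_off = TRUE` the
#' decay operator becomes the identity and `T1`/`T2` are ignored.
#'
#' @param T1 longitudinal relaxation time in ms (> 0).
#' @param T2 transverse relaxation time in ms (> 0). A value above `T1`
#'   triggers a warning (unphysical) but is not an error.
#' @param tau echo spacing in ms (> 0).
#' @param relaxation_off if `TRUE`, relaxation is disabled entirely.
#' @param regrowth if `TRUE`, longitudinal recovery towards equilibrium
#'   (the `(1 - exp(-t/T1)) M0` term) is added to `Z0` after each decay
#'   interval. The default (`FALSE`) is pure decay.
#' @return an object of class `tissue_params`.
#' @export
#' @examples
#' tissue_params(T1 = 1000, T2 = 150, tau = 10)
tissue_params <- function(T1 = 1000, T2 = 100, tau = 10,
                          relaxation_off = FALSE, regrowth = FALSE) {
  if (!relaxation_off) {
    if (!is.numeric(T1) || T1 <= 0) stop("T1 must be a positive number (ms)")
    if (!is.numeric(T2) || T2 <= 0) stop("T2 must be a positive number (ms)")
    if (!is.numeric(tau) || tau <= 0) stop("tau must be a positive number (ms)")
    if (T2 > T1) warning("T2 > T1 is unphysical for ordinary tissue")
  }
  structure(list(T1 = T1, T2 = T2, tau = tau,
                 relaxation_off = isTRUE(relaxation_off),
                 regrowth = isTRUE(regrowth)),
            class = "tissue_params")
}

#' Pulse train (amplitudes and phases)
#'
#' Index 1 is the excitation pulse; indices 2..N are the refocusing pulses
#' (pulse numbers 0 and 1..N-1 in the usual sequence-timing notation).
#' Angles are stored in radians internally; user interfaces use degrees.
#'
#' @param alpha pulse amplitudes (flip angles), length N, non-negative.
#' @param phi pulse phases, length N.
#' @param units `"degrees"` (default) or `"radians"` for the inputs.
#' @return an object of class `pulse_train` with radian fields `alpha`,
#'   `phi` and the train length `N`.
#' @export
#' @examples
#' pulse_train(c(90, rep(180, 5)), cpmg_phases(6))
pulse_train <- function(alpha, phi = NULL, units = c("degrees", "radians")) {
  units <- match.arg(units)
  if (is.null(phi)) phi <- rep(0, length(alpha))
  if (length(alpha) != length(phi))
    stop("alpha and phi must have equal length")
  if (any(!is.finite(alpha)) || any(!is.finite(phi)))
    stop("non-finite pulse parameters")
  if (units == "degrees") {
    alpha <- deg2rad(alpha)
    phi <- deg2rad(phi)
  }
  if (any(alpha < 0)) stop("pulse amplitudes must be non-negative")
  structure(list(alpha = as.numeric(alpha), phi = as.numeric(phi),
                 N = length(alpha)),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat("pulse_train with", x$N, "pulses (excitation + ", x$N - 1,
      "refocusing)\n")
  cat("  alpha [deg]:", paste(signif(rad2deg(x$alpha), 4), collapse = " "),
      "\n")
  cat("  phi   [deg]:", paste(signif(wrap_deg(rad2deg(x$phi)), 4),
                              collapse = " "), "\n")
  invisible(x)
}

#' CPMG phase convention
#'
#' Excitation phase 0 and refocusing phase 90 degrees (a 90 degree offset
#' between excitation and refocusing pulses).
#'
#' @param N train length (excitation + N-1 refocusing pulses).
#' @param units `"degrees"` (default) or `"radians"` for the output.
#' @return numeric vector of N phases.
#' @export
cpmg_phases <- function(N, units = c("degrees", "radians")) {
  units <- match.arg(units)
  out <- c(0, rep(90, N - 1))
  if (units == "radians") out <- deg2rad(out)
  out
}

#' EPG rotation operator
#'
#' The 3x3 complex block describing the action of a hard RF pulse with flip
#' angle `alpha` about an axis at phase `phi` on one configuration order
#' `(F_k^+, F_k^-, Z_k)`. The block is identical for every order, so the
#' full operator is block diagonal.
#'
#' @param alpha flip angle in radians.
#' @param phi pulse phase in radians.
#' @return a 3x3 complex matrix.
#' @export
#' @examples
#' rotation_operator(pi, pi / 2) # perfect refocusing about the y axis
rotation_operator <- function(alpha, phi) {
  ca2 <- cos(alpha / 2)^2
  sa2 <- sin(alpha / 2)^2
  sa <- sin(alpha)
  ep <- exp(1i * phi)
  em <- exp(-1i * phi)
  matrix(c(ca2,            em^2 * sa2,    -0.5i * em * sa,
           ep^2 * sa2,     ca2,            0.5i * ep * sa,
           -1i * ep * sa,  1i * em * sa,   cos(alpha)),
         nrow = 3, ncol = 3)
}

#' EPG relaxation (decay) operator
#'
#' Diagonal decay over a time interval: `diag(exp(-t/T2), exp(-t/T2),
#' exp(-t/T1))`. With `relaxation_off` set in the tissue parameters the
#' identity is returned. The interval defaults to the echo spacing but can
#' be any positive time (e.g. `tau/2` for half-period evolution).
#'
#' @param tissue a [tissue_params()] object.
#' @param interval evolution time in ms; defaults to `tissue$tau`.
#' @return a length-3 numeric vector of diagonal entries
#'   `(e2, e2, e1)`; use `diag()` to materialize the matrix.
#' @export
#' @examples
#' relaxation_operator(tissue_params(1000, 150, 150))
relaxation_operator <- function(tissue, interval = NULL) {
  if (tissue$relaxation_off) return(c(1, 1, 1))
  if (is.null(interval)) interval <- tissue$tau
  if (!is.numeric(interval) || interval < 0)
    stop("interval must be a non-negative time in ms")
  c(exp(-interval / tissue$T2), exp(-interval / tissue$T2),
    exp(-interval / tissue$T1))
}

#' Equilibrium configuration state
#'
#' @param K maximum retained configuration order.
#' @return an `epg_state`: all entries zero except `Z0 = 1`.
#' @export
epg_initial_state <- function(K) {
  mat <- matrix(0 + 0i, nrow = 3, ncol = K + 1)
  mat[3, 1] <- 1 + 0i
  structure(list(mat = mat, K = K), class = "epg_state")
}

#' Coerce a configuration state to the canonical vector ordering
#'
#' @param x an `epg_state`.
#' @param ... unused.
#' @return complex vector `(F0+, F0-, Z0, F1+, F1-, Z1, ...)` of length
#'   `3 (K + 1)`.
#' @export
as.vector.epg_state <- function(x, ...) as.vector(x$mat)

# internal: state from matrix
epg_state_from_mat <- function(mat) {
  structure(list(mat = mat, K = ncol(mat) - 1L), class = "epg_state")
}

#' Gradient-dephasing (shift) operator applied to a state
#'
#' Advances every transverse configuration one order up the integer ladder
#' (`F(k) -> F(k+1)`) while leaving the longitudinal configurations
#' untouched. In the stored half-ladder representation: `F_k^+` takes the
#' previous `F_(k-1)^+`, `F_k^-` takes `F_(k+1)^-`, and the new `F_0^+` is
#' the complex conjugate of the new `F_0^-`. Content shifted past order `K`
#' is discarded (truncation).
#'
#' @param state an `epg_state`.
#' @return the shifted `epg_state`.
#' @export
shift_apply <- function(state) {
  epg_state_from_mat(shift_mat(state$mat))
}

# internal fast path on the bare 3 x (K+1) matrix
shift_mat <- function(mat) {
  Kp1 <- ncol(mat)
  fp <- mat[1, ]
  fm <- mat[2, ]
  mat[1, ] <- c(Conj(fm[2]), fp[-Kp1])
  mat[2, ] <- c(fm[-1], 0 + 0i)
  if (Kp1 == 1L) { # degenerate K = 0: everything transverse is discarded
    mat[1, 1] <- 0 + 0i
    mat[2, 1] <- 0 + 0i
  }
  mat
}

# internal: half-period evolution S . E(tau/2) on the bare matrix
half_period_mat <- function(mat, ehalf, regrow = 0) {
  mat <- mat * ehalf # rows scale by (e2, e2, e1)
  if (regrow != 0) mat[3, 1] <- mat[3, 1] + regrow
  shift_mat(mat)
}

#' Build a per-period transition operator
#'
#' Returns the transition operator `P_n` of the discrete-time EPG system
#' `f_{n+1} = P_n f_n` as a structured action (never a dense matrix).
#' Composition `"excitation"` is a pure rotation (used for the first pulse,
#' applied to equilibrium). Composition `"interecho"` is
#' `[shift o decay(tau/2)] o rotation o [shift o decay(tau/2)]`: one
#' gradient-dephasing unit between pulse and echo on each side (CPMG
#' timing), which places each echo exactly at configuration order zero.
#'
#' @param alpha,phi pulse amplitude and phase in radians.
#' @param tissue a [tissue_params()] object.
#' @param K maximum configuration order.
#' @param composition `"excitation"` or `"interecho"`.
#' @return a function mapping an `epg_state` to an `epg_state`.
#' @export
build_period_operator <- function(alpha, phi, tissue, K,
                                  composition = c("interecho", "excitation")) {
  composition <- match.arg(composition)
  R3 <- rotation_operator(alpha, phi)
  if (composition == "excitation") {
    return(function(state) epg_state_from_mat(R3 %*% state$mat))
  }
  ehalf <- relaxation_operator(tissue, interval = tissue$tau / 2)
  regrow <- if (tissue$regrowth && !tissue$relaxation_off)
    (1 - exp(-tissue$tau / 2 / tissue$T1)) else 0
  function(state) {
    m <- half_period_mat(state$mat, ehalf, regrow)
    m <- R3 %*% m
    epg_state_from_mat(half_period_mat(m, ehalf, regrow))
  }
}

#' Default configuration-order truncation
#'
#' @param N train length.
#' @return `min(N, 25)`.
#' @export
default_K <- function(N) as.integer(min(N, 25L))

#' Forward EPG simulation of a pulse train
#'
#' Runs the discrete-time dynamical system `f_{n+1} = P_n f_n` from the
#' equilibrium state. Time index `n` runs 0..N: `n = 0` is equilibrium,
#' `n = 1` the state right after excitation, and `n = 2` the first echo.
#'
#' @param train a [pulse_train()].
#' @param tissue a [tissue_params()].
#' @param K maximum configuration order; default `min(N, 25)`.
#' @return an `epg_trajectory`: list of N+1 `epg_state`s with attributes.
#' @export
#' @examples
#' tr <- pulse_train(c(90, rep(180, 5)), cpmg_phases(6))
#' ti <- tissue_params(1000, 150, 10)
#' abs(echo_amplitudes(forward_simulate(tr, ti)))
forward_simulate <- function(train, tissue, K = NULL) {
  N <- train$N
  if (N < 2) stop("a train needs at least an excitation and one refocusing pulse")
  if (is.null(K)) K <- default_K(N)
  mats <- forward_mats(train$alpha, train$phi, tissue, K)
  traj <- lapply(mats, epg_state_from_mat)
  structure(traj, class = "epg_trajectory", K = K, N = N,
            tissue = tissue, train = train)
}

# internal: forward recursion on bare matrices; returns list of N+1 matrices.
# Runs through the same single-voxel kernel as the spatially resolved
# simulator, so a one-channel unit-sensitivity pTx simulation reproduces the
# standard path bit for bit.
forward_mats <- function(alpha, phi, tissue, K) {
  Z <- matrix(alpha * exp(1i * phi), ncol = 1)
  states <- forward_arrs(Z, tissue, K)
  lapply(states, function(A) matrix(A, 3, K + 1))
}

#' Echo amplitudes of a trajectory
#'
#' The echo at time `n` is read from the `F_0^-` component of `f_n` for
#' `n = 2..N` (the `F_0^+` component is its complex conjugate). Echoes are
#' indexed 1..N-1.
#'
#' @param trajectory an `epg_trajectory` from [forward_simulate()].
#' @return complex vector of N-1 echo values.
#' @export
echo_amplitudes <- function(trajectory) {
  N <- attr(trajectory, "N")
  vapply(trajectory[seq(3, N + 1)], function(s) s$mat[2, 1], complex(1))
}

#' Export an echo train as a data frame
#'
#' @param echoes complex echo values (from [echo_amplitudes()]).
#' @return data.frame with columns `echo_index`, `amplitude`, `phase_deg`.
#' @export
echo_table <- function(echoes) {
  data.frame(echo_index = seq_along(echoes),
             amplitude = Mod(echoes),
             phase_deg = wrap_deg(rad2deg(Arg(echoes))))
}

# ---------------------------------------------------------------------------
# EPG-pass accounting. Forward and adjoint recursions (and the derivative
# product loops) each cost about one EPG simulation; the counters make that
# accounting observable.
# ---------------------------------------------------------------------------
.pass_env <- new.env(parent = emptyenv())
.pass_env$forward <- 0L
.pass_env$backward <- 0L
.pass_env$derivative <- 0L

count_pass <- function(kind, n = 1L) {
  .pass_env[[kind]] <- .pass_env[[kind]] + as.integer(n)
  invisible(NULL)
}

#' Reset the EPG-pass counters
#' @return invisibly, the counters before the reset.
#' @export
reset_pass_counters <- function() {
  old <- pass_counters()
  .pass_env$forward <- 0L
  .pass_env$backward <- 0L
  .pass_env$derivative <- 0L
  invisible(old)
}

#' Read the EPG-pass counters
#' @return named integer vector with `forward`, `backward`, `derivative`
#'   pass counts and their `total`.
#' @export
pass_counters <- function() {
  c(forward = .pass_env$forward, backward = .pass_env$backward,
    derivative = .pass_env$derivative,
    total = .pass_env$forward + .pass_env$backward + .pass_env$derivative)
}
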