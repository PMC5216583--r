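# ---------------------------------------------------------------------------
# Exact derivatives via the adjoint-state method (ASM), plus a central
# finite-difference oracle.
#
# The shift operator is real-linear but not complex-linear (the new F0+ is
# the conjugate of the old F1-), so the adjoint recursion is carried out
# over the real field: covectors are complex row vectors lambda acting as
# v |-> Re(lambda . v), pullback through a complex-linear block is ordinary
# right-multiplication, and pullback through the conjugating entry of the
# shift deposits conj(lambda[F0+]) into the F1- slot. All reported
# gradients are Re(lambda . dP . f) and are exactly real.
# ---------------------------------------------------------------------------

#' Entrywise partial derivatives of the rotation operator
#'
#' Analytic derivatives of the 3x3 rotation block with respect to the flip
#' angle and the pulse phase, obtained by term-wise differentiation.
#'
#' @param alpha flip angle in radians.
#' @param phi pulse phase in radians.
#' @return list with 3x3 complex matrices `d_alpha` and `d_phi`.
#' @export
rotation_operator_partials <- function(alpha, phi) {
  s <- sin(alpha)
  c <- cos(alpha)
  sa2 <- sin(alpha / 2)^2
  ep <- exp(1i * phi)
  em <- exp(-1i * phi)
  d_alpha <- matrix(c(-s / 2,        em^2 * s / 2, -0.5i * em * c,
                      ep^2 * s / 2,  -s / 2,        0.5i * ep * c,
                      -1i * ep * c,  1i * em * c,  -s),
                    nrow = 3, ncol = 3)
  d_phi <- matrix(c(0,                -2i * em^2 * sa2, -0.5 * em * s,
                    2i * ep^2 * sa2,  0,                -0.5 * ep * s,
                    ep * s,           em * s,            0),
                  nrow = 3, ncol = 3)
  list(d_alpha = d_alpha, d_phi = d_phi)
}

# Wirtinger partials dR/dz and dR/dzbar of the rotation block written as a
# function of the complex effective pulse z = alpha * exp(i phi). Smooth at
# z = 0, which is what makes Cartesian pTx gradients well defined where the
# effective amplitude vanishes. Vectorized over z; returns 3 x 3 x m arrays.
rot_wirtinger_partials <- function(z) {
  m <- length(z)
  a <- Mod(z)
  zb <- Conj(z)
  small <- a < 1e-4
  s <- sin(a)
  cc <- cos(a)
  # u = sin^2(a/2)/a^2, v = sin(a)/a and the guarded quotients
  u <- ifelse(small, 0.25 - a^2 / 48, ifelse(a > 0, sin(a / 2)^2 / a^2, 0.25))
  v <- ifelse(small, 1 - a^2 / 6, ifelse(a > 0, s / a, 1))
  # up2a = u'(a)/(2a), vp2a = v'(a)/(2a), vav = v + a v'/2, s4a = s/(4a)
  up2a <- ifelse(small, -1 / 48 + a^2 / 720,
                 (s / (2 * a^2) - 2 * sin(a / 2)^2 / a^3) / (2 * a))
  vp2a <- ifelse(small, -1 / 6 + a^2 / 60, ((cc * a - s) / a^2) / (2 * a))
  vav <- v + a^2 * vp2a              # v + (a/2) v'
  s4a <- v / 4                       # sin(a)/(4a)
  s2a <- v / 2                       # sin(a)/(2a)
  Dz <- array(0i, c(3, 3, m))
  Dzb <- array(0i, c(3, 3, m))
  Dz[1, 1, ] <- -zb * s4a;        Dzb[1, 1, ] <- -z * s4a
  Dz[2, 2, ] <- -zb * s4a;        Dzb[2, 2, ] <- -z * s4a
  Dz[3, 3, ] <- -zb * s2a;        Dzb[3, 3, ] <- -z * s2a
  Dz[1, 2, ] <- 2 * z * u + z * a^2 * up2a   # 2 z u + z a u'/2
  Dzb[1, 2, ] <- z^3 * up2a
  Dz[2, 1, ] <- zb^3 * up2a
  Dzb[2, 1, ] <- 2 * zb * u + zb * a^2 * up2a
  Dz[1, 3, ] <- -1i * vav;        Dzb[1, 3, ] <- -1i * z^2 * vp2a
  Dz[2, 3, ] <- 1i * zb^2 * vp2a; Dzb[2, 3, ] <- 1i * vav
  Dz[3, 1, ] <- -0.5i * zb^2 * vp2a; Dzb[3, 1, ] <- -0.5i * vav
  Dz[3, 2, ] <- 0.5i * vav;       Dzb[3, 2, ] <- 0.5i * z^2 * vp2a
  list(Dz = Dz, Dzb = Dzb)
}

# ---- covector pullbacks (matrices are 3 x (K+1), unconjugated entries) ----

pullback_shift_mat <- function(L) {
  Kp1 <- ncol(L)
  lp <- L[1, ]
  lm <- L[2, ]
  if (Kp1 == 1L) {
    L[1, 1] <- 0 + 0i
    L[2, 1] <- 0 + 0i
    return(L)
  }
  L[1, ] <- c(lp[-1], 0 + 0i)
  newlm <- c(0 + 0i, lm[-Kp1])
  newlm[2] <- newlm[2] + Conj(lp[1])
  L[2, ] <- newlm
  L
}

pullback_half_mat <- function(L, ehalf) {
  pullback_shift_mat(L) * ehalf
}

pullback_period_mat <- function(L, R3, ehalf) {
  L <- pullback_half_mat(L, ehalf)
  L <- t(R3) %*% L
  pullback_half_mat(L, ehalf)
}

# per-echo seed weights for the quadratic objectives: the covector
# (f - t)^H C has the single nonzero entry c_n * conj(s_n - t_n) in the
# F0- slot; the signal-maximization seed is -c_n * conj(s_n).
seed_weights <- function(kind, echoes, target, weights) {
  switch(kind,
         error = weights * Conj(echoes - target),
         signal = -weights * Conj(echoes))
}

# which quadratic seed (if any) a functional uses
functional_seed_kind <- function(problem, of) {
  if (identical(of, "objective")) {
    switch(problem$objective,
           error_to_target = "error",
           maximize_signal = "signal",
           total_power = NULL)
  } else {
    cs <- problem$constraints[[of]]
    if (cs$type == "target_error") "error" else NULL
  }
}

#' Adjoint states of a trajectory
#'
#' Runs the backward recurrence for the adjoint row covectors:
#' `lambda_{N-1} = (f_N - t_N)^H C_N` and
#' `lambda_n = lambda_{n+1} P_{n+1} + (f_{n+1} - t_{n+1})^H C_{n+1}`,
#' with the seed generalized per objective (the signal-maximization seed is
#' `-f_{n+1}^H C_{n+1}`). One backward EPG-equivalent pass.
#'
#' @param trajectory an `epg_trajectory` from [forward_simulate()].
#' @param problem the [design_problem()] whose objective (or target-error
#'   constraint) defines the seed terms.
#' @param of `"objective"` (default) or the index of a `target_error`
#'   constraint.
#' @return an `adjoint_sequence`: list of N covector matrices
#'   `lambda_0 .. lambda_{N-1}`, each 3 x (K+1) complex, in state-matrix
#'   layout (flatten column-major for the canonical vector ordering).
#' @export
adjoint_states <- function(trajectory, problem, of = "objective") {
  train <- attr(trajectory, "train")
  tissue <- attr(trajectory, "tissue")
  N <- attr(trajectory, "N")
  K <- attr(trajectory, "K")
  kind <- functional_seed_kind(problem, of)
  if (is.null(kind))
    stop("the selected functional has no implicit (trajectory) dependence")
  echoes <- echo_amplitudes(trajectory)
  w <- seed_weights(kind, echoes, problem$target, problem$weights)
  lams <- backward_adjoints(train$alpha, train$phi, tissue, K, w)
  structure(lams, class = "adjoint_sequence", N = N, K = K)
}

# internal backward recursion on seed weights w (length N-1, echo n at f_{n+1})
backward_adjoints <- function(alpha, phi, tissue, K, w) {
  N <- length(alpha)
  ehalf <- relaxation_operator(tissue, interval = tissue$tau / 2)
  seedmat <- function(wn) {
    m <- matrix(0 + 0i, 3, K + 1)
    m[2, 1] <- wn
    m
  }
  lams <- vector("list", N)
  L <- seedmat(w[N - 1])
  lams[[N]] <- L
  for (n in seq(N - 2, 0)) {
    R3 <- rotation_operator(alpha[n + 2], phi[n + 2])
    L <- pullback_period_mat(L, R3, ehalf)
    if (n + 1 >= 2) L <- L + seedmat(w[n])
    lams[[n + 1]] <- L
  }
  count_pass("backward")
  lams
}

# ASM gradient of a quadratic functional for a standard train.
# Returns per-pulse d_alpha, d_phi (implicit part only).
asm_core_standard <- function(alpha, phi, tissue, K, kind, target, weights) {
  N <- length(alpha)
  mats <- forward_mats(alpha, phi, tissue, K)              # pass 1
  echoes <- vapply(mats[seq(3, N + 1)], function(m) m[2, 1], complex(1))
  w <- seed_weights(kind, echoes, target, weights)
  lams <- backward_adjoints(alpha, phi, tissue, K, w)      # pass 2
  ehalf <- relaxation_operator(tissue, interval = tissue$tau / 2)
  regrow <- if (tissue$regrowth && !tissue$relaxation_off)
    (1 - exp(-tissue$tau / 2 / tissue$T1)) else 0
  d_alpha <- numeric(N)
  d_phi <- numeric(N)
  # excitation: P_0 is the bare rotation
  parts <- rotation_operator_partials(alpha[1], phi[1])
  d_alpha[1] <- Re(sum(lams[[1]] * (parts$d_alpha %*% mats[[1]])))
  d_phi[1] <- Re(sum(lams[[1]] * (parts$d_phi %*% mats[[1]])))
  # refocusing pulses: P_n = half . R . half; only R depends on (alpha, phi)
  for (n in seq_len(N - 1)) {
    h <- half_period_mat(mats[[n + 1]], ehalf, regrow)
    kap <- pullback_half_mat(lams[[n + 1]], ehalf)
    parts <- rotation_operator_partials(alpha[n + 1], phi[n + 1])
    d_alpha[n + 1] <- Re(sum(kap * (parts$d_alpha %*% h)))
    d_phi[n + 1] <- Re(sum(kap * (parts$d_phi %*% h)))
  }
  count_pass("derivative", 2L)                             # passes 3 and 4
  list(d_alpha = d_alpha, d_phi = d_phi, echoes = echoes)
}

#' Exact gradient of an objective or constraint via the adjoint-state method
#'
#' Computes the exact derivatives of the selected functional with respect to
#' all per-pulse design variables: `(alpha_n, phi_n)` for a standard train
#' or the per-channel Cartesian weights `(x_{n,l}, y_{n,l})` for a pTx
#' drive. Implicit (trajectory) dependence is handled by one forward pass,
#' one backward adjoint pass and one combined derivative-product loop
#' costing two more passes — four EPG-recursion-equivalent passes in total,
#' independent of the number of design parameters. Explicit dependence
#' (power terms) is added analytically at no EPG cost.
#'
#' @param problem a [design_problem()].
#' @param x a [pulse_train()] (standard mode) or `channel_drive` (pTx).
#' @param of `"objective"` (default) or the index of a scalar constraint
#'   (`total_power` or `target_error`) in `problem$constraints`.
#' @return a `gradient_report`: list with `d_alpha`/`d_phi` (standard) or
#'   `d_x`/`d_y` (N x L matrices, pTx), the functional `value`, and
#'   `epg_pass_count`.
#' @export
gradient_asm <- function(problem, x, of = "objective") {
  passes0 <- pass_counters()[["total"]]
  kind <- functional_seed_kind(problem, of)
  if (problem$mode == "standard") {
    if (!inherits(x, "pulse_train")) stop("standard mode expects a pulse_train")
    N <- x$N
    d_alpha <- numeric(N)
    d_phi <- numeric(N)
    value <- NULL
    if (!is.null(kind)) {
      core <- asm_core_standard(x$alpha, x$phi, problem$tissue, problem$K,
                                kind, problem$target, problem$weights)
      d_alpha <- core$d_alpha
      d_phi <- core$d_phi
      value <- quadratic_value(kind, core$echoes, problem$target,
                               problem$weights)
    }
    expl <- explicit_terms_standard(problem, x, of)
    d_alpha <- d_alpha + expl$d_alpha
    value <- (if (is.null(value)) 0 else value) + expl$value
    rep <- list(d_alpha = d_alpha, d_phi = d_phi, value = value)
  } else {
    if (!inherits(x, "channel_drive")) stop("pTx mode expects a channel_drive")
    core <- asm_core_ptx(x, problem$fields, problem$tissue, problem$K,
                         kind, problem$target, problem$weights)
    d_x <- core$d_x
    d_y <- core$d_y
    value <- if (is.null(kind)) 0 else
      quadratic_value(kind, core$echoes, problem$target, problem$weights)
    expl <- explicit_terms_ptx(problem, x, of)
    d_x <- d_x + expl$d_x
    d_y <- d_y + expl$d_y
    value <- value + expl$value
    rep <- list(d_x = d_x, d_y = d_y, value = value)
  }
  rep$epg_pass_count <- pass_counters()[["total"]] - passes0
  rep$method <- "asm"
  class(rep) <- "gradient_report"
  rep
}

# value of the quadratic functionals given echoes (vector or matrix)
quadratic_value <- function(kind, echoes, target, weights) {
  switch(kind,
         error = error_objective(echoes, target, weights),
         signal = signal_objective(echoes, weights))
}

# explicit-dependence contributions (Eq.-14 style terms)
explicit_terms_standard <- function(problem, x, of) {
  d_alpha <- numeric(x$N)
  value <- 0
  uses_power <-
    (identical(of, "objective") && problem$objective == "total_power") ||
    (!identical(of, "objective") &&
       problem$constraints[[of]]$type == "total_power")
  if (uses_power) {
    d_alpha <- x$alpha
    value <- total_power(x)
    if (!identical(of, "objective"))
      value <- value - problem$constraints[[of]]$power_max
  }
  if (!identical(of, "objective") &&
      problem$constraints[[of]]$type == "target_error")
    value <- -problem$constraints[[of]]$sigma^2
  list(d_alpha = d_alpha, value = value)
}

explicit_terms_ptx <- function(problem, x, of) {
  d_x <- matrix(0, nrow(x$x), ncol(x$x))
  d_y <- d_x
  value <- 0
  uses_power <-
    (identical(of, "objective") && problem$objective == "total_power") ||
    (!identical(of, "objective") &&
       problem$constraints[[of]]$type == "total_power")
  if (uses_power) {
    d_x <- x$x
    d_y <- x$y
    value <- total_power(x)
    if (!identical(of, "objective"))
      value <- value - problem$constraints[[of]]$power_max
  }
  if (!identical(of, "objective") &&
      problem$constraints[[of]]$type == "target_error")
    value <- -problem$constraints[[of]]$sigma^2
  list(d_x = d_x, d_y = d_y, value = value)
}

# scalar functional value (objective or indexed scalar constraint)
functional_value <- function(problem, x, of = "objective") {
  if (identical(of, "objective")) return(evaluate_objective(problem, x))
  cs <- problem$constraints[[of]]
  switch(cs$type,
    total_power = total_power(x) - cs$power_max,
    target_error = error_objective(problem_echoes(problem, x),
                                   problem$target, problem$weights) -
      cs$sigma^2,
    stop("finite-difference/ASM gradients are defined for scalar functionals"))
}

#' Central finite-difference gradient oracle
#'
#' Approximates the same gradient as [gradient_asm()] by central
#' differences on every design variable. Costs `2 Np + 1` forward
#' EPG simulations (baseline plus two per parameter), which is what the
#' adjoint-state method avoids.
#'
#' @inheritParams gradient_asm
#' @param delta finite-difference step in radians (default `1e-6`).
#' @param scheme optional [build_grouping()] scheme: differences are then
#'   taken on the grouped variables and grouped gradients are returned.
#' @return a `gradient_report` (fields as in [gradient_asm()], with
#'   `epg_pass_count = 2 Np + 1`).
#' @export
gradient_fd_oracle <- function(problem, x, of = "objective", delta = 1e-6,
                               scheme = NULL) {
  if (delta <= 0) stop("delta must be positive")
  passes0 <- pass_counters()[["total"]]
  value <- functional_value(problem, x, of)   # baseline (counted if implicit)
  fd_pair <- function(make) {
    (functional_value(problem, make(delta), of) -
       functional_value(problem, make(-delta), of)) / (2 * delta)
  }
  if (problem$mode == "standard") {
    N <- x$N
    if (is.null(scheme)) scheme <- singleton_grouping(N)
    G <- scheme$G
    d_alpha <- numeric(G)
    d_phi <- numeric(G)
    for (j in seq_len(G)) {
      idx <- scheme$groups[[j]]
      d_alpha[j] <- fd_pair(function(d) {
        tr <- x; tr$alpha[idx] <- tr$alpha[idx] + d; tr
      })
      d_phi[j] <- fd_pair(function(d) {
        tr <- x; tr$phi[idx] <- tr$phi[idx] + d; tr
      })
    }
    rep <- list(d_alpha = d_alpha, d_phi = d_phi, value = value)
    np <- 2L * G
  } else {
    N <- nrow(x$x)
    L <- ncol(x$x)
    if (is.null(scheme)) scheme <- singleton_grouping(N)
    G <- scheme$G
    d_x <- matrix(0, G, L)
    d_y <- matrix(0, G, L)
    for (j in seq_len(G)) {
      idx <- scheme$groups[[j]]
      for (l in seq_len(L)) {
        d_x[j, l] <- fd_pair(function(d) {
          dr <- x; dr$x[idx, l] <- dr$x[idx, l] + d; dr
        })
        d_y[j, l] <- fd_pair(function(d) {
          dr <- x; dr$y[idx, l] <- dr$y[idx, l] + d; dr
        })
      }
    }
    rep <- list(d_x = d_x, d_y = d_y, value = value)
    np <- 2L * G * L
  }
  used <- pass_counters()[["total"]] - passes0
  rep$epg_pass_count <- if (used > 0) used else 2L * np + 1L
  rep$n_parameters <- np
  rep$method <- "fd"
  class(rep) <- "gradient_report"
  rep
}

# does the selected functional depend on the trajectory?
uses_trajectory <- function(problem, of) {
  !is.null(functional_seed_kind(problem, of))
}

#' @export
print.gradient_report <- function(x, ...) {
  cat("gradient_report (", x$method, "): value =", format(x$value),
      ", EPG-equivalent passes =", x$epg_pass_count, "\n")
  invisible(x)
}

#' Serialize a gradient report to JSON
#'
#' @param report a `gradient_report`.
#' @return a JSON string (deterministic field order).
#' @export
gradient_report_json <- function(report) {
  payload <- list(method = report$method, value = report$value,
                  epg_pass_count = report$epg_pass_count)
  for (f in c("d_alpha", "d_phi", "d_x", "d_y"))
    if (!is.null(report[[f]])) payload[[f]] <- report[[f]]
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}
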