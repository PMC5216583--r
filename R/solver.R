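# ---------------------------------------------------------------------------
# Constrained minimization driver.
#
# Box constraints (amplitude non-negativity and, in standard mode, peak
# amplitude caps) are handled natively by L-BFGS-B; nonlinear inequality
# constraints (total power, target error, pTx per-channel peak power) by an
# augmented-Lagrangian outer loop with multiplier updates. All gradients
# are exact: adjoint-state for trajectory-dependent terms, analytic for
# explicit power terms. The quasi-Newton inner solver (L-BFGS-B) supplies
# the BFGS-style curvature model. Everything is deterministic.
# ---------------------------------------------------------------------------

#' Solver options
#'
#' @param max_iterations total inner-iteration budget across all
#'   augmented-Lagrangian rounds (default 200; the pTx presets halt at 50).
#' @param gradient_tolerance projected-gradient tolerance of the inner
#'   solver (`pgtol`).
#' @param constraint_tolerance feasibility tolerance; nonlinear constraints
#'   are also tightened internally by this margin so that reported
#'   solutions are (strictly) feasible for the true constraints.
#' @param hessian curvature model; `"bfgs"` (limited-memory, via L-BFGS-B).
#' @param seed integer; consumed only by synthetic inputs, never by the
#'   solver itself.
#' @param penalty_init,penalty_growth initial augmented-Lagrangian penalty
#'   and its growth factor when feasibility stalls.
#' @param max_outer maximum number of multiplier updates.
#' @param factr relative objective-change tolerance of L-BFGS-B.
#' @param lmm number of BFGS correction pairs retained by the inner solver
#'   (the limited-memory curvature model; larger values converge in fewer
#'   iterations on ill-conditioned trains).
#' @return an object of class `solver_options`.
#' @export
solver_options <- function(max_iterations = 200L, gradient_tolerance = 1e-8,
                           constraint_tolerance = 1e-9,
                           hessian = c("bfgs"), seed = NULL,
                           penalty_init = 10, penalty_growth = 10,
                           max_outer = 40L, factr = 10, lmm = 40L) {
  hessian <- match.arg(hessian)
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (gradient_tolerance <= 0 || constraint_tolerance <= 0)
    stop("tolerances must be positive")
  structure(list(max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 constraint_tolerance = constraint_tolerance,
                 hessian = hessian, seed = seed,
                 penalty_init = penalty_init,
                 penalty_growth = penalty_growth,
                 max_outer = as.integer(max_outer), factr = factr,
                 lmm = as.integer(lmm)),
            class = "solver_options")
}

# ---- variable packing -----------------------------------------------------

# Build the packed nonlinear program for a problem + initial point.
# `free` marks which grouped parameters are optimized; fixed ones keep the
# initial values. Standard mode packs (a_free, b_free); pTx packs the free
# rows of the grouped Cartesian weights.
make_nlp <- function(problem, init, scheme, free, options) {
  N <- problem$N
  if (is.null(scheme)) scheme <- singleton_grouping(N)
  G <- scheme$G
  firsts <- vapply(scheme$groups, function(g) g[1], integer(1))
  if (problem$mode == "standard") {
    if (!inherits(init, "pulse_train")) stop("standard mode expects a pulse_train")
    if (init$N != N) stop("initial train length disagrees with the problem")
    if (is.null(free)) free <- list()
    free_a <- if (is.null(free$alpha)) rep(TRUE, G) else free$alpha
    free_b <- if (is.null(free$phi)) rep(TRUE, G) else free$phi
    a0 <- init$alpha[firsts]
    b0 <- init$phi[firsts]
    # peak-amplitude caps become box bounds on the grouped amplitudes
    ub_a <- rep(Inf, G)
    for (cs in problem$constraints) {
      if (cs$type != "peak_amplitude") next
      pulses <- if (isFALSE(cs$include_excitation)) 2:N else 1:N
      capped <- vapply(scheme$groups, function(g) all(g %in% pulses),
                       logical(1))
      mixed <- vapply(scheme$groups, function(g)
        any(g %in% pulses) && !all(g %in% pulses), logical(1))
      if (any(mixed))
        stop("a group mixes capped and uncapped pulses; split the grouping")
      ub_a[capped] <- pmin(ub_a[capped], cs$alpha_max)
    }
    theta0 <- c(a0[free_a], b0[free_b])
    lower <- c(rep(0, sum(free_a)), rep(-Inf, sum(free_b)))
    upper <- c(ub_a[free_a], rep(Inf, sum(free_b)))
    na <- sum(free_a)
    unpack <- function(theta) {
      a <- a0; b <- b0
      a[free_a] <- theta[seq_len(na)]
      b[free_b] <- theta[na + seq_len(sum(free_b))]
      pulse_train(expand_grouped(scheme, a), expand_grouped(scheme, b),
                  units = "radians")
    }
    pack_grad <- function(d_alpha, d_phi) {
      c(project_gradient(scheme, d_alpha)[free_a],
        project_gradient(scheme, d_phi)[free_b])
    }
    grouped_of <- function(x) list(alpha = x$alpha[firsts],
                                   phi = x$phi[firsts])
  } else {
    if (!inherits(init, "channel_drive")) stop("pTx mode expects a channel_drive")
    L <- problem$fields$L
    if (init$N != N) stop("initial drive length disagrees with the problem")
    if (is.null(free)) free <- list()
    free_g <- if (is.null(free$drive)) rep(TRUE, G) else free$drive
    ax0 <- init$x[firsts, , drop = FALSE]
    ay0 <- init$y[firsts, , drop = FALSE]
    nfree <- sum(free_g)
    theta0 <- c(as.vector(ax0[free_g, ]), as.vector(ay0[free_g, ]))
    lower <- rep(-Inf, length(theta0))
    upper <- rep(Inf, length(theta0))
    unpack <- function(theta) {
      ax <- ax0; ay <- ay0
      ax[free_g, ] <- matrix(theta[seq_len(nfree * L)], nfree, L)
      ay[free_g, ] <- matrix(theta[nfree * L + seq_len(nfree * L)], nfree, L)
      channel_drive(ax[scheme$index, , drop = FALSE],
                    ay[scheme$index, , drop = FALSE])
    }
    pack_grad <- function(d_x, d_y) {
      gx <- rowsum(d_x, scheme$index, reorder = TRUE)
      gy <- rowsum(d_y, scheme$index, reorder = TRUE)
      c(as.vector(gx[free_g, ]), as.vector(gy[free_g, ]))
    }
    grouped_of <- function(x) list(x = x$x[firsts, , drop = FALSE],
                                   y = x$y[firsts, , drop = FALSE])
  }
  # nonlinear inequality constraints handled by the outer loop
  nl_idx <- which(vapply(problem$constraints, function(cs)
    cs$type %in% c("total_power", "target_error") ||
      (cs$type == "peak_amplitude" && problem$mode == "ptx"), logical(1)))
  eval_point <- function(theta) {
    x <- unpack(theta)
    gr <- gradient_asm(problem, x, of = "objective")
    f <- gr$value
    gf <- if (problem$mode == "standard") pack_grad(gr$d_alpha, gr$d_phi)
    else pack_grad(gr$d_x, gr$d_y)
    cons <- list()
    cgr <- list()
    for (i in nl_idx) {
      cs <- problem$constraints[[i]]
      if (cs$type == "peak_amplitude") { # pTx quadratic, vector-valued
        cons[[as.character(i)]] <- as.vector(x$x^2 + x$y^2) - cs$alpha_max^2
        cgr[[as.character(i)]] <- local({
          xx <- x
          function(v) { # gradient of sum_i v_i c_i
            vm <- matrix(v, nrow(xx$x), ncol(xx$x))
            pack_grad(2 * vm * xx$x, 2 * vm * xx$y)
          }
        })
      } else {
        g2 <- gradient_asm(problem, x, of = i)
        cons[[as.character(i)]] <- g2$value
        cgr[[as.character(i)]] <- local({
          gg <- g2
          if (problem$mode == "standard") {
            gpacked <- pack_grad(gg$d_alpha, gg$d_phi)
            function(v) v * gpacked
          } else {
            gpacked <- pack_grad(gg$d_x, gg$d_y)
            function(v) v * gpacked
          }
        })
      }
    }
    list(x = x, f = f, gf = gf, cons = cons, cgr = cgr)
  }
  list(theta0 = theta0, lower = lower, upper = upper, unpack = unpack,
       pack_grad = pack_grad, eval_point = eval_point, nl_idx = nl_idx,
       grouped_of = grouped_of, scheme = scheme)
}

#' Solve a sequence-design problem
#'
#' Gradient-based constrained minimization with exact adjoint-state
#' gradients. Amplitude non-negativity and standard-mode peak-amplitude
#' caps are enforced as box bounds; remaining inequality constraints by an
#' augmented-Lagrangian loop with L-BFGS-B inner solves. Deterministic
#' given inputs and options.
#'
#' @param problem a [design_problem()].
#' @param init initial [pulse_train()] (standard) or [channel_drive()]
#'   (pTx), dimensioned to the full train; grouped variables start from the
#'   value at the first pulse of each group.
#' @param scheme optional [build_grouping()] scheme (default: every pulse
#'   free).
#' @param options a [solver_options()].
#' @param free optional list of logical vectors over groups selecting the
#'   optimized variables: `alpha`/`phi` (standard mode) or `drive` (pTx);
#'   unselected variables keep their initial values.
#' @return an object of class `solve_result` with the optimized train or
#'   drive (`x`), grouped parameters, objective value and history, the
#'   merit value before/after every inner solve (`merit_history`), true
#'   constraint values, iteration count (inner gradient evaluations) and
#'   EPG-pass totals.
#' @export
solve_design <- function(problem, init, scheme = NULL,
                         options = solver_options(), free = NULL) {
  passes0 <- pass_counters()[["total"]]
  nlp <- make_nlp(problem, init, scheme, free, options)
  ncons <- length(nlp$nl_idx)
  margin <- options$constraint_tolerance
  theta <- nlp$theta0
  budget <- options$max_iterations
  used <- 0L
  history <- numeric(0)
  cache <- new.env(parent = emptyenv())
  cached_eval <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$ev)
    ev <- nlp$eval_point(theta)
    cache$theta <- theta
    cache$ev <- ev
    ev
  }
  merit <- NULL # one (before, after) row per inner solve
  if (ncons == 0L) {
    f0 <- cached_eval(theta)$f
    res <- stats::optim(theta,
      fn = function(th) cached_eval(th)$f,
      gr = function(th) cached_eval(th)$gf,
      method = "L-BFGS-B", lower = nlp$lower, upper = nlp$upper,
      control = list(maxit = budget, factr = options$factr,
                     pgtol = options$gradient_tolerance,
                     lmm = options$lmm))
    theta <- res$par
    used <- unname(res$counts[2])
    history <- c(f0, res$value)
    merit <- rbind(merit, c(before = f0, after = res$value))
    converged <- res$convergence == 0
    lam <- list()
  } else {
    ev0 <- cached_eval(theta)
    lam <- lapply(ev0$cons, function(cv) rep(0, length(cv)))
    mu <- options$penalty_init
    prev_viol <- Inf
    converged <- FALSE
    for (outer in seq_len(options$max_outer)) {
      aug_f <- function(th) {
        ev <- cached_eval(th)
        pen <- 0
        for (k in names(ev$cons)) {
          t_ <- pmax(0, lam[[k]] / mu + ev$cons[[k]] + margin)
          pen <- pen + (mu / 2) * sum(t_^2)
        }
        ev$f + pen
      }
      aug_g <- function(th) {
        ev <- cached_eval(th)
        g <- ev$gf
        for (k in names(ev$cons)) {
          v <- mu * pmax(0, lam[[k]] / mu + ev$cons[[k]] + margin)
          if (any(v != 0)) g <- g + ev$cgr[[k]](v)
        }
        g
      }
      m_before <- aug_f(theta)
      res <- stats::optim(theta, fn = aug_f, gr = aug_g,
        method = "L-BFGS-B", lower = nlp$lower, upper = nlp$upper,
        control = list(maxit = max(1L, budget - used),
                       factr = options$factr,
                       pgtol = options$gradient_tolerance,
                       lmm = options$lmm))
      theta <- res$par
      merit <- rbind(merit, c(before = m_before, after = res$value))
      used <- used + unname(res$counts[2])
      ev <- cached_eval(theta)
      history <- c(history, ev$f)
      viol <- max(0, unlist(lapply(ev$cons, function(cv) max(cv + margin))))
      for (k in names(ev$cons))
        lam[[k]] <- pmax(0, lam[[k]] + mu * (ev$cons[[k]] + margin))
      if (viol <= 0.1 * margin && res$convergence == 0) {
        converged <- TRUE
        break
      }
      if (used >= budget) break
      if (viol > 0.25 * prev_viol) mu <- mu * options$penalty_growth
      prev_viol <- viol
    }
  }
  ev <- cached_eval(theta)
  x <- ev$x
  cons_true <- evaluate_constraints(problem, x)
  max_viol <- if (length(cons_true)) max(0, unlist(cons_true)) else 0
  structure(list(x = x, grouped = nlp$grouped_of(x),
                 scheme = nlp$scheme,
                 objective = ev$f, objective_history = history,
                 merit_history = merit,
                 constraint_values = cons_true,
                 max_violation = max_viol,
                 iterations = used, converged = converged,
                 multipliers = lam,
                 epg_pass_count = pass_counters()[["total"]] - passes0),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("solve_result: objective =", format(x$objective),
      "| iterations =", x$iterations,
      "| max constraint violation =", format(x$max_violation),
      "| EPG passes =", x$epg_pass_count, "\n")
  if (inherits(x$x, "pulse_train")) print(x$x)
  else cat("  pTx drive:", x$x$N, "pulses x", x$x$L, "channels\n")
  invisible(x)
}

#' Write a solve result to JSON and CSV files
#'
#' Writes `summary.json` (objective, violations, iteration and pass
#' counts) and a train table `train.csv` (standard mode: per-pulse
#' amplitude and phase in degrees) or drive tables `drive_x.csv` /
#' `drive_y.csv` (pTx mode).
#'
#' @param result a [solve_design()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_solve_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(objective = result$objective,
               objective_history = result$objective_history,
               constraint_values = result$constraint_values,
               max_violation = result$max_violation,
               iterations = result$iterations,
               converged = result$converged,
               epg_pass_count = result$epg_pass_count)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (inherits(result$x, "pulse_train")) {
    utils::write.csv(data.frame(
      pulse = seq_len(result$x$N) - 1L,
      alpha_deg = rad2deg(result$x$alpha),
      phi_deg = wrap_deg(rad2deg(result$x$phi))),
      file.path(dir, "train.csv"), row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(result$x$x),
                     file.path(dir, "drive_x.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(result$x$y),
                     file.path(dir, "drive_y.csv"), row.names = FALSE)
  }
  invisible(dir)
}
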