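# ---------------------------------------------------------------------------
# Preset design experiments. Five presets mirror the canonical numerical
# tests of EPG-based optimal-control sequence design: recovery of the
# 90/180 CPMG train by signal maximization, minimum-power constant-signal
# trains, peak-constrained designs recovering the CPMG phase condition,
# and pTx signal-homogenization designs on synthetic 8-channel maps.
# ---------------------------------------------------------------------------

#' Names of the bundled experiment presets
#' @return character vector of preset names.
#' @export
preset_names <- function() {
  c("test1_max_signal", "test2_constant_intensity", "test3_capped_60",
    "test3_time_varying", "test4_ptx3d_synthetic", "test5_ptx2d_synthetic")
}

# Reference flip-angle trains (degrees) used by the pTx presets: published
# pseudo-steady-state trains; the last amplitude is repeated in the actual
# scan beyond the designed horizon, so only the designed pulses appear.
alpha_standard_3d <- function() c(90, 151, 90, 67, rep(60, 48))
alpha_standard_2d <- function() c(105, 174, 145, rep(140, 7))

# build the full specification of one preset (problem, init, scheme,
# options, metadata), honouring overrides
preset_spec <- function(name, overrides = list(), seed = 1L) {
  ov <- function(key, default) if (!is.null(overrides[[key]]))
    overrides[[key]] else default
  switch(name,
    test1_max_signal = {
      N <- ov("N", 60L)
      tissue <- tissue_params(T1 = ov("T1", 1000), T2 = ov("T2", 150),
                              tau = ov("tau", 10))
      list(problem = design_problem("maximize_signal", N = N, tissue = tissue),
           init = pulse_train(c(90, rep(60, N - 1)), cpmg_phases(N)),
           scheme = NULL, free = NULL,
           options = solver_options(max_iterations = ov("max_iter", 2000L)),
           label = "unconstrained signal maximization (expects 90/180 CPMG)")
    },
    test2_constant_intensity = {
      N <- ov("N", 50L)
      ic <- ov("ic", 0.6)
      sigma <- ov("sigma", 1e-3)
      tissue <- tissue_params(tau = 10, relaxation_off = TRUE)
      # CPMG echoes lie on the +i axis under this phase convention
      target <- rep(1i * ic, N - 1)
      problem <- design_problem(
        "total_power", N = N, tissue = tissue, target = target,
        constraints = list(list(type = "target_error", sigma = sigma)))
      G <- N
      list(problem = problem,
           init = pulse_train(c(90, rep(18, N - 1)), cpmg_phases(N)),
           scheme = NULL,
           free = list(alpha = c(FALSE, rep(TRUE, G - 1)),
                       phi = rep(FALSE, G)),
           options = solver_options(max_iterations = ov("max_iter", 1500L)),
           label = sprintf(
             "minimum-power constant signal intensity I_c = %.2f", ic))
    },
    test3_capped_60 = {
      N <- ov("N", 60L)
      tissue <- tissue_params(T1 = ov("T1", 1000), T2 = ov("T2", 150),
                              tau = ov("tau", 10))
      weights <- c(rep(0, 5), rep(1, N - 6)) # only echoes 6+ count
      problem <- design_problem(
        "maximize_signal", N = N, tissue = tissue, weights = weights,
        constraints = list(list(type = "peak_amplitude",
                                alpha_max = deg2rad(60),
                                include_excitation = FALSE)))
      scheme <- build_grouping(list(1, 2:N), N)
      # all-zero starting phases sit on a reflection-symmetry saddle of the
      # objective; a small initial refocusing-phase offset breaks it
      init <- pulse_train(c(90, rep(60, N - 1)),
                          c(0, rep(ov("phi_perturb", 10), N - 1)))
      list(problem = problem, init = init, scheme = scheme, free = NULL,
           options = solver_options(max_iterations = ov("max_iter", 500L)),
           label = "peak-capped constant refocusing (expects CPMG recovery)")
    },
    test3_time_varying = {
      N <- ov("N", 60L)
      tissue <- tissue_params(T1 = ov("T1", 1000), T2 = ov("T2", 150),
                              tau = ov("tau", 10))
      weights <- c(rep(0, 5), rep(1, N - 6))
      problem <- design_problem(
        "maximize_signal", N = N, tissue = tissue, weights = weights,
        constraints = list(list(type = "peak_amplitude",
                                alpha_max = deg2rad(60),
                                include_excitation = FALSE)))
      init <- pulse_train(c(90, rep(60, N - 1)),
                          c(0, rep(ov("phi_perturb", 10), N - 1)))
      list(problem = problem, init = init, scheme = NULL, free = NULL,
           options = solver_options(max_iterations = ov("max_iter", 1000L)),
           label = "peak-capped time-varying refocusing train")
    },
    test4_ptx3d_synthetic = {
      L <- ov("L", 8L)
      grid <- ov("grid", c(25L, 25L, 25L))
      fields <- synth_field_maps(L, grid, profile = "headcoil", seed = seed)
      fields <- subsample_roi(fields, mode = ov("subsample", "tetrahedral"),
                              factor = ov("factor", 5L))
      tissue <- tissue_params(T1 = 500, T2 = 400, tau = 2.9)
      a_std <- alpha_standard_3d()
      N <- length(a_std)
      target <- epg_of_train(a_std, cpmg_phases(N), tissue)
      nominal <- pulse_train(a_std, cpmg_phases(N))
      init <- cp_mode_drive(nominal, fields)
      pmax_ <- 2 * total_power(init)
      problem <- design_problem(
        "error_to_target", N = N, tissue = tissue, target = target,
        fields = fields,
        constraints = list(
          list(type = "peak_amplitude", alpha_max = deg2rad(270)),
          list(type = "total_power", power_max = pmax_)))
      scheme <- build_grouping(c(as.list(1:22), list(23:32, 33:42, 43:52)), N)
      list(problem = problem, init = init, scheme = scheme, free = NULL,
           options = solver_options(max_iterations = ov("max_iter", 50L),
                                    seed = seed),
           label = "8-channel 3D pTx signal homogenization (synthetic maps)")
    },
    test5_ptx2d_synthetic = {
      L <- ov("L", 8L)
      grid <- ov("grid", c(51L, 51L))
      fields <- synth_field_maps(L, grid, profile = "headcoil", seed = seed)
      fields <- subsample_roi(fields, mode = ov("subsample", "stride"),
                              factor = ov("factor", 4L))
      tissue <- tissue_params(T1 = 1500, T2 = 100, tau = 12)
      a_std <- alpha_standard_2d()
      N <- length(a_std)
      target <- epg_of_train(a_std, cpmg_phases(N), tissue)
      weights <- rep(1, N - 1)
      weights[5] <- 2 # central k-space echo
      nominal <- pulse_train(a_std, cpmg_phases(N))
      init <- cp_mode_drive(nominal, fields)
      pmax_ <- 2 * total_power(init)
      problem <- design_problem(
        "error_to_target", N = N, tissue = tissue, target = target,
        weights = weights, fields = fields,
        constraints = list(
          list(type = "peak_amplitude", alpha_max = deg2rad(270)),
          list(type = "total_power", power_max = pmax_)))
      list(problem = problem, init = init, scheme = NULL, free = NULL,
           options = solver_options(max_iterations = ov("max_iter", 50L),
                                    seed = seed),
           label = "8-channel 2D pTx signal homogenization (synthetic maps)")
    },
    stop("unknown preset: ", name)
  )
}

# relative standard deviation of |echo| across ROI voxels, per echo
rel_std_per_echo <- function(echoes) {
  m <- Mod(as.matrix(echoes))
  apply(m, 1, function(r) stats::sd(r) / mean(r))
}

#' Run a preset design experiment end to end
#'
#' Builds the preset's design problem, solves it, collects summary metrics
#' and (optionally) writes train/echo tables and a JSON summary.
#'
#' @param name one of [preset_names()].
#' @param overrides named list overriding preset parameters (e.g. `ic`,
#'   `max_iter`, `N`, `factor`).
#' @param output_dir optional directory for report files.
#' @param seed integer seed (consumed only by the synthetic field-map
#'   generator of the pTx presets).
#' @return an object of class `preset_run` with the problem, solve result
#'   and a `metrics` list.
#' @export
run_preset <- function(name, overrides = list(), output_dir = NULL,
                       seed = 1L) {
  name <- match.arg(name, preset_names())
  spec <- preset_spec(name, overrides, seed = seed)
  result <- solve_design(spec$problem, spec$init, scheme = spec$scheme,
                         options = spec$options, free = spec$free)
  metrics <- list(label = spec$label,
                  objective = result$objective,
                  iterations = result$iterations,
                  epg_pass_count = result$epg_pass_count,
                  max_violation = result$max_violation)
  if (spec$problem$mode == "standard") {
    tr <- result$x
    echoes <- echo_amplitudes(
      forward_simulate(tr, spec$problem$tissue, spec$problem$K))
    metrics$refocusing_deg <- rad2deg(tr$alpha[-1])
    metrics$excitation_deg <- rad2deg(tr$alpha[1])
    metrics$phase_offset_deg <-
      abs(wrap_deg(rad2deg(tr$phi[-1] - tr$phi[1])))
    if (!is.null(spec$problem$target))
      metrics$target_rmse <- sqrt(max(0, error_objective(
        matrix(echoes, ncol = 1), spec$problem$target,
        rep(1, length(echoes)))))
    metrics$echoes <- echoes
  } else {
    fwd0 <- spatial_forward(spec$init, spec$problem$fields,
                            spec$problem$tissue, spec$problem$K)
    fwd1 <- spatial_forward(result$x, spec$problem$fields,
                            spec$problem$tissue, spec$problem$K)
    metrics$n_voxels <- spec$problem$fields$R
    sch <- if (is.null(spec$scheme)) singleton_grouping(spec$problem$N)
    else spec$scheme
    metrics$n_parameters <- count_design_parameters(
      sch, L = spec$problem$fields$L, ptx = TRUE)
    metrics$rel_std_initial <- rel_std_per_echo(fwd0$echoes)
    metrics$rel_std_optimized <- rel_std_per_echo(fwd1$echoes)
    metrics$echoes_initial <- fwd0$echoes
    metrics$echoes_optimized <- fwd1$echoes
  }
  run <- structure(list(name = name, problem = spec$problem,
                        scheme = spec$scheme, init = spec$init,
                        result = result, metrics = metrics),
                   class = "preset_run")
  if (!is.null(output_dir)) write_preset_run(run, output_dir)
  run
}

# write report files for one run
write_preset_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_solve_result(run$result, dir)
  m <- run$metrics
  if (run$problem$mode == "standard") {
    utils::write.csv(echo_table(m$echoes), file.path(dir, "echoes.csv"),
                     row.names = FALSE)
  } else {
    export_echoes_csv(m$echoes_initial, file.path(dir, "echoes_initial.csv"))
    export_echoes_csv(m$echoes_optimized,
                      file.path(dir, "echoes_optimized.csv"))
  }
  keep <- !vapply(m, is.complex, logical(1)) &
    !names(m) %in% c("echoes", "echoes_initial", "echoes_optimized")
  jsonlite::write_json(c(list(preset = run$name), m[keep]),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.preset_run <- function(x, ...) {
  cat(report(list(x)), sep = "\n")
  invisible(x)
}

#' Human-readable summary of preset runs
#'
#' Tabulates objective values, refocusing amplitudes/phase offsets or
#' per-echo relative standard deviations across voxels, design-parameter
#' counts and EPG-pass totals.
#'
#' @param results list of `preset_run` objects (possibly empty).
#' @return character vector of report lines.
#' @export
report <- function(results) {
  out <- character(0)
  for (run in results) {
    m <- run$metrics
    out <- c(out, sprintf("== %s: %s", run$name, m$label),
             sprintf("   objective %.6g after %d iterations (%d EPG passes), max violation %.3g",
                     m$objective, m$iterations, m$epg_pass_count,
                     m$max_violation))
    if (run$problem$mode == "standard") {
      out <- c(out, sprintf(
        "   excitation %.2f deg; refocusing %.2f-%.2f deg; phase offset %.2f-%.2f deg",
        m$excitation_deg, min(m$refocusing_deg), max(m$refocusing_deg),
        min(m$phase_offset_deg), max(m$phase_offset_deg)))
      if (!is.null(m$target_rmse))
        out <- c(out, sprintf("   rms deviation from target: %.3g",
                              m$target_rmse))
    } else {
      out <- c(out, sprintf("   %d design parameters, %d ROI voxels",
                            m$n_parameters, m$n_voxels),
               sprintf("   per-echo relative std: initial %.3f-%.3f, optimized %.3f-%.3f (improved for %d/%d echoes)",
                       min(m$rel_std_initial), max(m$rel_std_initial),
                       min(m$rel_std_optimized), max(m$rel_std_optimized),
                       sum(m$rel_std_optimized < m$rel_std_initial),
                       length(m$rel_std_initial)))
    }
  }
  out
}
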