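# Building-block objectives, constraints and parameter grouping.

test_that("error and signal objectives evaluate the weighted quadratics", {
  tgt <- c(0.5 + 0i, 0.2 + 0.1i)
  expect_equal(error_objective(tgt, tgt), 0)
  expect_equal(error_objective(0.6 + 0i, 0.5 + 0i, weights = 2), 0.01)
  expect_error(error_objective(tgt, tgt, weights = c(-1, 1)), "negative")
  expect_equal(signal_objective(c(0 + 0i, 0 + 0i)), 0)
  # five unit echoes with unit weights: -2.5
  off <- tissue_params(relaxation_off = TRUE)
  e <- echo_amplitudes(forward_simulate(
    pulse_train(c(90, rep(180, 5)), cpmg_phases(6)), off))
  expect_equal(signal_objective(e), -2.5, tolerance = 1e-12)
  # masking the first five echoes leaves only the tail in the value
  e9 <- complex(real = 1:9 / 10)
  w <- c(rep(0, 5), rep(1, 4))
  expect_equal(signal_objective(e9, w), -0.5 * sum((6:9 / 10)^2))
  # multi-voxel matrices sum over voxels
  em <- cbind(e9, e9)
  expect_equal(signal_objective(em, w), 2 * signal_objective(e9, w))
})

test_that("total power and peak constraints use the standard quadratic forms", {
  expect_equal(total_power(pulse_train(c(0, 0), c(0, 0))), 0)
  tr <- pulse_train(c(pi / 2, pi), c(0, 0), units = "radians")
  expect_equal(total_power(tr), 0.5 * (pi^2 / 4 + pi^2))
  dr <- channel_drive(matrix(c(pi / 2, 0), 1, 2), matrix(0, 1, 2))
  expect_equal(total_power(dr), pi^2 / 8)
  # standard peak: alpha_j - alpha_max, in excess for a 70 vs 60 deg bound
  tr2 <- pulse_train(c(90, 70, 60), c(0, 0, 0))
  pc <- peak_constraints(tr2, 60 * pi / 180, include_excitation = FALSE)
  expect_equal(pc, (c(70, 60) - 60) * pi / 180, tolerance = 1e-12)
  expect_equal(peak_constraints(pulse_train(c(60, 60), c(0, 0)),
                                60 * pi / 180),
               c(0, 0), tolerance = 1e-12)
  # pTx peak: x^2 + y^2 - alpha_max^2 per pulse and channel
  dr2 <- channel_drive(matrix(1:4, 2, 2), matrix(0, 2, 2))
  expect_equal(peak_constraints(dr2, 2), c(1, 4, 9, 16) - 4)
  # amplitude-only dependence: phases do not move power or peak values
  tr3 <- pulse_train(c(90, 70, 60), c(10, -50, 120))
  expect_equal(total_power(tr3), total_power(tr2))
  expect_equal(peak_constraints(tr3, 1), peak_constraints(tr2, 1))
})

test_that("grouping schemes build the printed incidence structure", {
  sch <- build_grouping(list(1, 2, 3:5, 6:7), N = 7)
  expect_equal(dim(sch$Q), c(7L, 4L))
  expect_equal(sch$Q,
               matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0,
                        0, 0, 1, 0,
                        0, 0, 1, 0,
                        0, 0, 1, 0,
                        0, 0, 0, 1,
                        0, 0, 0, 1), 7, 4, byrow = TRUE),
               ignore_attr = TRUE)
  expect_identical(count_design_parameters(sch), 8L)
  a <- c(10, 20, 30, 40)
  expect_equal(expand_grouped(sch, a), c(10, 20, 30, 30, 30, 40, 40))
  expect_equal(project_gradient(sch, rep(1, 7)), c(1, 1, 3, 2))
  # singleton grouping is the identity
  s1 <- singleton_grouping(5)
  expect_equal(s1$Q, diag(5), ignore_attr = TRUE)
  expect_identical(count_design_parameters(s1), 10L)
  expect_error(build_grouping(list(1:3, 3:5), N = 5), "partition")
  expect_error(build_grouping(list(1:3), N = 5), "partition")
})

test_that("parameter bookkeeping covers the pTx grouping schemes", {
  # 22 individually driven pulses + 3 groups of 10, 8 channels -> 400
  sch4 <- build_grouping(c(as.list(1:22), list(23:32, 33:42, 43:52)), 52)
  expect_identical(count_design_parameters(sch4, L = 8, ptx = TRUE), 400L)
  expect_identical(count_design_parameters(singleton_grouping(60)), 120L)
})

test_that("grouped ASM gradients match grouped finite differences", {
  set.seed(91)
  N <- 9
  ti <- tissue_params(900, 130, 8)
  tr0 <- pulse_train(runif(N, 20, 160), runif(N, -180, 180))
  sch <- build_grouping(list(1, 2:4, 5:9), N)
  # make the train constant on groups so grouped differencing is consistent
  tr <- pulse_train(expand_grouped(sch, tr0$alpha[c(1, 2, 5)]),
                    expand_grouped(sch, tr0$phi[c(1, 2, 5)]),
                    units = "radians")
  target <- complex(real = runif(N - 1, -0.4, 0.4),
                    imaginary = runif(N - 1, -0.4, 0.4))
  pr <- design_problem("error_to_target", N = N, tissue = ti, target = target)
  ga <- gradient_asm(pr, tr)
  proj <- c(project_gradient(sch, ga$d_alpha), project_gradient(sch, ga$d_phi))
  gf <- gradient_fd_oracle(pr, tr, scheme = sch)
  fd <- c(gf$d_alpha, gf$d_phi)
  expect_lt(max(abs(proj - fd)) / max(abs(fd)), 1e-6)
})

test_that("optimizing grouped variables equals the group-constrained optimum", {
  # 4-pulse toy: exhaustive grid search over the two grouped amplitudes
  # against the solver operating in the grouped space
  ti <- tissue_params(relaxation_off = TRUE)
  N <- 4
  pr <- design_problem("maximize_signal", N = N, tissue = ti)
  sch <- build_grouping(list(1, 2:4), N)
  grid <- seq(0, pi, length.out = 121)
  best <- Inf
  for (a0 in grid) for (a1 in grid) {
    tr <- pulse_train(expand_grouped(sch, c(a0, a1)),
                      cpmg_phases(N, units = "radians"), units = "radians")
    v <- evaluate_objective(pr, tr)
    if (v < best) best <- v
  }
  res <- solve_design(pr, pulse_train(c(45, 45, 45, 45), cpmg_phases(N)),
                      scheme = sch,
                      free = list(phi = c(FALSE, FALSE)),
                      options = solver_options(max_iterations = 300))
  expect_lt(res$objective, best + 1e-3)
  expect_equal(res$objective, -1.5, tolerance = 1e-3) # three unit echoes
})

test_that("design problems validate their inputs", {
  ti <- tissue_params(1000, 150, 10)
  expect_error(design_problem("error_to_target", N = 5, tissue = ti),
               "target")
  expect_error(design_problem("maximize_signal", N = 5, tissue = ti,
                              weights = c(-1, 1, 1, 1)), "negative")
  expect_error(design_problem("maximize_signal", N = 5, tissue = ti,
                              constraints = list(list(type = "nope"))),
               "unknown constraint")
  expect_error(design_problem("total_power", N = 5, tissue = ti,
                              constraints = list(
                                list(type = "target_error", sigma = 0.1))),
               "target")
  # objective and constraint values are finite reals on finite input
  tr <- pulse_train(runif(5, 0, 180), runif(5, -180, 180))
  pr <- design_problem("maximize_signal", N = 5, tissue = ti,
                       constraints = list(
                         list(type = "peak_amplitude", alpha_max = 1),
                         list(type = "total_power", power_max = 2)))
  expect_true(is.finite(evaluate_objective(pr, tr)))
  expect_true(all(is.finite(unlist(evaluate_constraints(pr, tr)))))
  expect_gte(total_power(tr), 0)
})

test_that("reference-train targets come from the ideal EPG response", {
  ti <- tissue_params(500, 400, 2.9)
  a <- c(90, 151, 90, 67, rep(60, 3))
  tgt <- epg_of_train(a, tissue = ti)
  direct <- echo_amplitudes(forward_simulate(
    pulse_train(a, cpmg_phases(length(a))), ti))
  expect_identical(tgt, direct)
})
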