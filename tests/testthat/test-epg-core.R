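# Forward EPG model: operators, state bookkeeping, echo extraction.

test_that("rotation operator matches closed forms and conserves energy", {
  expect_equal(rotation_operator(0, 1.234), diag(3) + 0i)
  expect_equal(rotation_operator(pi, pi / 2),
               matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1) + 0i, 3, 3,
                      byrow = TRUE),
               tolerance = 1e-14)
  expect_equal(rotation_operator(pi / 2, 0),
               matrix(c(0.5, 0.5, -1i, 0.5, 0.5, 1i, -0.5i, 0.5i, 0), 3, 3,
                      byrow = TRUE),
               tolerance = 1e-14)
  # (|w1|^2 + |w2|^2)/2 + |w3|^2 is invariant under every rotation
  set.seed(11)
  for (i in 1:25) {
    v <- complex(real = rnorm(3), imaginary = rnorm(3))
    w <- rotation_operator(runif(1, 0, 2 * pi), runif(1, -pi, pi)) %*% v
    en <- function(u) (Mod(u[1])^2 + Mod(u[2])^2) / 2 + Mod(u[3])^2
    expect_lt(abs(en(w) - en(v)), 1e-12)
  }
})

test_that("relaxation operator is the stated diagonal decay", {
  ti <- tissue_params(T1 = 1000, T2 = 150, tau = 150)
  expect_equal(relaxation_operator(ti),
               c(exp(-1), exp(-1), exp(-0.15)))
  expect_equal(relaxation_operator(ti, interval = 0), c(1, 1, 1))
  off <- tissue_params(relaxation_off = TRUE)
  expect_equal(relaxation_operator(off), c(1, 1, 1))
  expect_error(tissue_params(T1 = -5), "T1")
  expect_error(tissue_params(T2 = 0), "T2")
  expect_error(tissue_params(tau = -1), "tau")
  expect_warning(tissue_params(T1 = 100, T2 = 500), "unphysical")
})

test_that("shift operator climbs the configuration ladder correctly", {
  K <- 4
  s <- epg_initial_state(K)
  # transverse content at order zero moves to F1+ (with F0 refilled by
  # conjugate symmetry from the vacated ladder)
  s$mat[1, 1] <- 1 + 0i
  s$mat[2, 1] <- 1 + 0i
  s$mat[3, 1] <- 0
  out <- shift_apply(s)
  expect_equal(out$mat[1, 2], 1 + 0i)
  expect_equal(out$mat[1, 1], 0 + 0i)
  expect_equal(out$mat[2, 1], 0 + 0i)
  # longitudinal configurations are untouched
  s2 <- epg_initial_state(K)
  s2$mat[3, 1] <- 0
  s2$mat[3, 4] <- 0.4 + 0i
  expect_equal(shift_apply(s2)$mat, s2$mat)
  # F1- feeds F0- and the conjugate fills F0+
  s3 <- epg_initial_state(K)
  s3$mat[3, 1] <- 0
  cc <- 0.3 - 0.7i
  s3$mat[2, 2] <- cc
  out3 <- shift_apply(s3)
  expect_equal(out3$mat[2, 1], cc)
  expect_equal(out3$mat[1, 1], Conj(cc))
  # canonical flattening follows the interleaved (F+, F-, Z) ordering
  expect_equal(as.vector(epg_initial_state(1)),
               c(0, 0, 1, 0, 0, 0) + 0i)
})

test_that("period operator compositions behave as rotation and CPMG period", {
  ti <- tissue_params(relaxation_off = TRUE)
  exc <- build_period_operator(pi / 2, 0, ti, K = 3,
                               composition = "excitation")
  f1 <- exc(epg_initial_state(3))
  expect_equal(f1$mat[, 1], rotation_operator(pi / 2, 0)[, 3],
               tolerance = 1e-14)
  # two perfect refocusing periods after 90 deg excitation: |F0-| = 1 twice
  per <- build_period_operator(pi, pi / 2, ti, K = 3)
  f2 <- per(f1)
  f3 <- per(f2)
  expect_equal(Mod(f2$mat[2, 1]), 1, tolerance = 1e-12)
  expect_equal(Mod(f3$mat[2, 1]), 1, tolerance = 1e-12)
  # with relaxation, the first echo of a 180 pulse decays by exp(-tau/T2)
  ti2 <- tissue_params(T1 = 1000, T2 = 150, tau = 12)
  exc2 <- build_period_operator(pi / 2, 0, ti2, K = 3,
                                composition = "excitation")
  per2 <- build_period_operator(pi, pi / 2, ti2, K = 3)
  e1 <- per2(exc2(epg_initial_state(3)))
  expect_equal(Mod(e1$mat[2, 1]), exp(-12 / 150), tolerance = 1e-12)
  expect_error(build_period_operator(1, 0, ti, 3, composition = "nonsense"))
})

test_that("forward simulation reproduces ideal CPMG and the sin^2 echo", {
  off <- tissue_params(relaxation_off = TRUE)
  tr <- pulse_train(c(90, rep(180, 5)), cpmg_phases(6))
  e <- echo_amplitudes(forward_simulate(tr, off))
  expect_equal(Mod(e), rep(1, 5), tolerance = 1e-12)
  # 90/120: first echo amplitude sin^2(60 deg) = 0.75 (isochromat oracle)
  tr2 <- pulse_train(c(90, 120), cpmg_phases(2))
  e2 <- echo_amplitudes(forward_simulate(tr2, off))
  iso <- isochromat_echoes(c(pi / 2, 2 * pi / 3), c(0, pi / 2),
                           relaxation_off = TRUE)
  expect_equal(Mod(e2), 0.75, tolerance = 1e-12)
  expect_equal(e2, iso, tolerance = 1e-12)
  # CPMG decay: echo j has magnitude exp(-tau j / T2)
  ti <- tissue_params(T1 = 1e12, T2 = 150, tau = 10)
  e3 <- echo_amplitudes(forward_simulate(tr, ti))
  expect_equal(Mod(e3), exp(-10 * (1:5) / 150), tolerance = 1e-12)
  expect_error(forward_simulate(pulse_train(90), off), "at least")
})

test_that("truncation order K does not alter reachable states", {
  # the CPMG timing applies two dephasing units per interecho period, so
  # N periods populate configuration orders up to 2(N-1); any K at or
  # beyond that bound gives identical trajectories
  set.seed(21)
  N <- 9
  tr <- pulse_train(runif(N, 20, 170), runif(N, -180, 180))
  ti <- tissue_params(800, 90, 7)
  tA <- forward_simulate(tr, ti, K = 2 * N)
  tB <- forward_simulate(tr, ti, K = 3 * N)
  tC <- forward_simulate(tr, ti, K = 2 * N + 10)
  for (n in seq_along(tA)) {
    shared <- seq_len(2 * N + 1)
    expect_lt(max(Mod(tA[[n]]$mat - tB[[n]]$mat[, seq_len(2 * N + 1)])),
              1e-12)
    expect_lt(max(Mod(tB[[n]]$mat[, shared] - tC[[n]]$mat[, shared])), 1e-12)
  }
  expect_identical(attr(forward_simulate(tr, ti), "K"), 9L)
  expect_identical(default_K(60), 25L)
})

test_that("conjugate symmetry F0+ = conj(F0-) holds along trajectories", {
  set.seed(31)
  for (rep in 1:5) {
    N <- sample(3:10, 1)
    tr <- pulse_train(runif(N, 0, 180), runif(N, -180, 180))
    ti <- tissue_params(runif(1, 300, 2000), runif(1, 40, 300),
                        runif(1, 3, 20))
    traj <- forward_simulate(tr, ti)
    for (s in traj)
      expect_lt(Mod(s$mat[1, 1] - Conj(s$mat[2, 1])), 1e-12)
  }
})

test_that("state energy never grows over a pulse-free period with relaxation", {
  set.seed(41)
  ti <- tissue_params(900, 80, 15)
  tr <- pulse_train(runif(6, 30, 160), runif(6, -180, 180))
  traj <- forward_simulate(tr, ti)
  energy <- function(m) sum(Mod(m[1:2, ])^2) / 2 + sum(Mod(m[3, ])^2)
  per <- build_period_operator(0, 0, ti, K = attr(traj, "K"))
  for (s in traj) {
    expect_lte(energy(per(s)$mat), energy(s$mat) + 1e-12)
  }
})

test_that("forward EPG matches the isochromat ensemble on random trains", {
  set.seed(51)
  for (rep in 1:8) {
    N <- sample(3:12, 1)
    a <- runif(N, 0, pi)
    p <- runif(N, -pi, pi)
    relax_off <- rep %% 2 == 0
    ti <- tissue_params(runif(1, 400, 2000), runif(1, 40, 350),
                        runif(1, 4, 20), relaxation_off = relax_off)
    e_epg <- echo_amplitudes(
      forward_simulate(pulse_train(a, p, units = "radians"), ti))
    e_iso <- isochromat_echoes(a, p, ti$T1, ti$T2, ti$tau,
                               relaxation_off = relax_off)
    expect_lt(max(Mod(e_epg - e_iso)), 1e-6)
  }
})

test_that("longitudinal regrowth is off by default and opt-in", {
  ti <- tissue_params(500, 100, 50)
  ti_re <- tissue_params(500, 100, 50, regrowth = TRUE)
  # low-angle refocusing barely disturbs Z, so regrowth accumulates
  tr <- pulse_train(c(90, rep(10, 5)), cpmg_phases(6))
  t_pure <- forward_simulate(tr, ti)
  t_re <- forward_simulate(tr, ti_re)
  expect_lt(Mod(t_pure[[7]]$mat[3, 1]), 0.01)
  expect_gt(Re(t_re[[7]]$mat[3, 1]), 0.1)
  # regrown magnetization converted by a refocusing pulse rephases at the
  # pulse times, not the echo centres, so the sampled echoes are unchanged
  expect_equal(echo_amplitudes(t_re), echo_amplitudes(t_pure),
               tolerance = 1e-12)
})

test_that("echo tables carry deterministic columns", {
  tr <- pulse_train(c(90, 180, 180), cpmg_phases(3))
  e <- echo_amplitudes(forward_simulate(tr, tissue_params(1000, 150, 10)))
  tab <- echo_table(e)
  expect_identical(names(tab), c("echo_index", "amplitude", "phase_deg"))
  expect_equal(tab$echo_index, 1:2)
  expect_equal(tab$amplitude, Mod(e))
  # all-zero train produces zero echoes
  z <- pulse_train(c(0, 0, 0), c(0, 0, 0))
  ez <- echo_amplitudes(forward_simulate(z, tissue_params(1000, 150, 10)))
  expect_equal(Mod(ez), c(0, 0))
})
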