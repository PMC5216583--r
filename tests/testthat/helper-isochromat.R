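# Independent isochromat-ensemble oracle: simulates an ensemble of spins
# with uniformly distributed dephasing angles using plain 3x3 real
# rotations, and reads each echo as the ensemble average of M- = Mx - i My.
# Timing matches the interecho convention of the package: one dephasing
# unit between pulse and echo on each side, so each isochromat precesses
# its angle theta once per half period. With >= 720 uniformly spaced
# angles the discrete Fourier average is exact to machine precision for
# the configuration orders reachable by short trains.

isochromat_echoes <- function(alpha, phi, T1 = Inf, T2 = Inf, tau = 0,
                              relaxation_off = FALSE, n_iso = 720) {
  rot <- function(a, p) {
    cz <- cos(p); sz <- sin(p)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    ca <- cos(a); sa <- sin(a)
    Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
    Rz %*% Rx %*% t(Rz)
  }
  e2 <- if (relaxation_off) 1 else exp(-tau / 2 / T2)
  e1 <- if (relaxation_off) 1 else exp(-tau / 2 / T1)
  th <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  N <- length(alpha)
  # state: 3 x n_iso, start at equilibrium
  M <- rbind(0, 0, rep(1, n_iso))
  M <- rot(alpha[1], phi[1]) %*% M
  half <- function(M) {
    M[1:2, ] <- M[1:2, ] * e2
    M[3, ] <- M[3, ] * e1
    mp <- complex(real = M[1, ], imaginary = M[2, ]) * exp(1i * th)
    M[1, ] <- Re(mp)
    M[2, ] <- Im(mp)
    M
  }
  echoes <- complex(N - 1)
  for (n in seq_len(N - 1)) {
    M <- half(M)
    M <- rot(alpha[n + 1], phi[n + 1]) %*% M
    M <- half(M)
    echoes[n] <- mean(complex(real = M[1, ], imaginary = -M[2, ]))
  }
  echoes
}
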