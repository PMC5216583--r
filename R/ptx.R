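# ---------------------------------------------------------------------------
# Spatially resolved EPG for parallel transmit: effective-pulse mapping,
# per-voxel forward/adjoint simulation (vectorized over the ROI), ROI
# subsampling, and a synthetic multi-channel transmit-field generator.
# ---------------------------------------------------------------------------

#' Multi-channel transmit-field set
#'
#' Per-voxel complex transmit sensitivities for L channels over a region of
#' interest. Sensitivities are dimensionless scalings of the nominal flip
#' angle. Voxel coordinates are 0-based integer indices in axis order
#' (x, y, z); the ROI mask is implied by the voxel list.
#'
#' @param B complex R x L matrix of sensitivities (R voxels, L channels).
#' @param coords integer R x 3 matrix of voxel coordinates (0-based).
#' @param dims integer length-3 grid shape.
#' @return an object of class `transmit_field_set`.
#' @export
transmit_field_set <- function(B, coords, dims) {
  B <- as.matrix(B)
  coords <- as.matrix(coords)
  if (nrow(B) < 1) stop("the ROI must contain at least one voxel")
  if (nrow(coords) != nrow(B)) stop("coords and B must have matching rows")
  if (ncol(coords) != 3) stop("coords must have three columns (x, y, z)")
  if (any(!is.finite(Mod(B)))) stop("sensitivities must be finite")
  structure(list(B = B, coords = coords, dims = as.integer(dims),
                 R = nrow(B), L = ncol(B)),
            class = "transmit_field_set")
}

#' @export
print.transmit_field_set <- function(x, ...) {
  cat("transmit_field_set:", x$L, "channels,", x$R, "ROI voxels, grid",
      paste(x$dims, collapse = "x"), "\n")
  invisible(x)
}

#' Per-pulse, per-channel drive weights
#'
#' Cartesian (real/imaginary) per-channel RF weights in nominal flip-angle
#' units (radians): row n is pulse n-1 (row 1 = excitation), column l is
#' channel l.
#'
#' @param x,y real N x L matrices.
#' @return an object of class `channel_drive`.
#' @export
channel_drive <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical shape")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("drive weights must be finite")
  structure(list(x = x, y = y, N = nrow(x), L = ncol(x)),
            class = "channel_drive")
}

#' Effective pulse seen by one voxel
#'
#' The effective amplitude and phase are modulus and argument of the sum of
#' the complex channel weights scaled by the conjugated channel
#' sensitivities: `z = sum_l B_l^* (x_l + i y_l)`. A vanishing sum gives
#' amplitude 0 and phase 0 by convention (gradients are taken in Cartesian
#' form, which is smooth there).
#'
#' @param x,y real per-channel weights, length L.
#' @param B complex sensitivities at the voxel, length L.
#' @return named numeric vector `c(alpha = , phi = )` in radians.
#' @export
effective_pulse <- function(x, y, B) {
  z <- sum(Conj(B) * complex(real = x, imaginary = y))
  c(alpha = Mod(z), phi = if (Mod(z) > 0) Arg(z) else 0)
}

# internal: N x R matrix of complex effective pulses for a drive
effective_z <- function(drive, fields) {
  W <- drive$x + 1i * drive$y
  W %*% t(Conj(fields$B))
}

# rotation entries as smooth functions of the complex effective pulse z,
# vectorized over voxels; returns a list of 9 length-R complex vectors
rot_entries_z <- function(z) {
  a <- Mod(z)
  small <- a < 1e-4
  u <- ifelse(small, 0.25 - a^2 / 48, ifelse(a > 0, sin(a / 2)^2 / a^2, 0.25))
  v <- ifelse(small, 1 - a^2 / 6, ifelse(a > 0, sin(a) / a, 1))
  zb <- Conj(z)
  list(r11 = complex(real = cos(a / 2)^2), r12 = z^2 * u, r13 = -1i * z * v,
       r21 = zb^2 * u, r22 = complex(real = cos(a / 2)^2), r23 = 1i * zb * v,
       r31 = -0.5i * zb * v, r32 = 0.5i * z * v,
       r33 = complex(real = cos(a)))
}

# ---- array helpers: states over voxels stored as 3 x (K+1) x R arrays ----

arr_plane <- function(A, i) {
  d <- dim(A)
  matrix(A[i, , ], d[2], d[3])
}

# multiply each voxel's (K+1)-column by a per-voxel scalar
vox_scale <- function(M, s) M * rep(s, each = nrow(M))

apply_rot_arr <- function(A, re, transpose = FALSE) {
  F1 <- arr_plane(A, 1); F2 <- arr_plane(A, 2); F3 <- arr_plane(A, 3)
  if (!transpose) {
    N1 <- vox_scale(F1, re$r11) + vox_scale(F2, re$r12) + vox_scale(F3, re$r13)
    N2 <- vox_scale(F1, re$r21) + vox_scale(F2, re$r22) + vox_scale(F3, re$r23)
    N3 <- vox_scale(F1, re$r31) + vox_scale(F2, re$r32) + vox_scale(F3, re$r33)
  } else { # covector pullback: right-multiplication by the block
    N1 <- vox_scale(F1, re$r11) + vox_scale(F2, re$r21) + vox_scale(F3, re$r31)
    N2 <- vox_scale(F1, re$r12) + vox_scale(F2, re$r22) + vox_scale(F3, re$r32)
    N3 <- vox_scale(F1, re$r13) + vox_scale(F2, re$r23) + vox_scale(F3, re$r33)
  }
  A[1, , ] <- N1; A[2, , ] <- N2; A[3, , ] <- N3
  A
}

shift_arr <- function(A) {
  d <- dim(A)
  Kp1 <- d[2]
  Fp <- arr_plane(A, 1); Fm <- arr_plane(A, 2)
  if (Kp1 == 1L) {
    A[1, , ] <- 0 + 0i; A[2, , ] <- 0 + 0i
    return(A)
  }
  A[1, , ] <- rbind(Conj(Fm[2, , drop = FALSE]), Fp[-Kp1, , drop = FALSE])
  A[2, , ] <- rbind(Fm[-1, , drop = FALSE],
                    matrix(0 + 0i, 1, d[3]))
  A
}

pullback_shift_arr <- function(A) {
  d <- dim(A)
  Kp1 <- d[2]
  Lp <- arr_plane(A, 1); Lm <- arr_plane(A, 2)
  if (Kp1 == 1L) {
    A[1, , ] <- 0 + 0i; A[2, , ] <- 0 + 0i
    return(A)
  }
  A[1, , ] <- rbind(Lp[-1, , drop = FALSE], matrix(0 + 0i, 1, d[3]))
  newLm <- rbind(matrix(0 + 0i, 1, d[3]), Lm[-Kp1, , drop = FALSE])
  newLm[2, ] <- newLm[2, ] + Conj(Lp[1, ])
  A[2, , ] <- newLm
  A
}

half_arr <- function(A, ehalf, regrow = 0) {
  A <- A * ehalf
  if (regrow != 0) A[3, 1, ] <- A[3, 1, ] + regrow
  shift_arr(A)
}

pullback_half_arr <- function(A, ehalf) pullback_shift_arr(A) * ehalf

# forward recursion for all voxels; Z is the N x R effective-pulse matrix
forward_arrs <- function(Z, tissue, K) {
  N <- nrow(Z)
  R <- ncol(Z)
  ehalf <- relaxation_operator(tissue, interval = tissue$tau / 2)
  regrow <- if (tissue$regrowth && !tissue$relaxation_off)
    (1 - exp(-tissue$tau / 2 / tissue$T1)) else 0
  out <- vector("list", N + 1)
  A <- array(0 + 0i, c(3, K + 1, R))
  A[3, 1, ] <- 1 + 0i
  out[[1]] <- A
  A <- apply_rot_arr(A, rot_entries_z(Z[1, ]))
  out[[2]] <- A
  for (n in seq_len(N - 1)) {
    A <- half_arr(A, ehalf, regrow)
    A <- apply_rot_arr(A, rot_entries_z(Z[n + 1, ]))
    A <- half_arr(A, ehalf, regrow)
    out[[n + 2]] <- A
  }
  count_pass("forward")
  out
}

# echoes (N-1) x R from a list of state arrays
arr_echoes <- function(states) {
  N <- length(states) - 1L
  R <- dim(states[[1]])[3]
  em <- vapply(states[seq(3, N + 1)], function(A) A[2, 1, ], complex(R))
  if (is.null(dim(em))) em <- matrix(em, nrow = R)
  t(em)
}

#' Spatially resolved forward EPG over an ROI
#'
#' Maps a channel drive to per-voxel effective pulses and simulates the EPG
#' in every ROI voxel. With one channel and unit sensitivities this reduces
#' exactly to the standard single-channel simulation.
#'
#' @param drive a [channel_drive()].
#' @param fields a [transmit_field_set()].
#' @param tissue a [tissue_params()].
#' @param K maximum configuration order; default `min(N, 25)`.
#' @return a list with `echoes` ((N-1) x R complex matrix), `alpha` and
#'   `phi` (N x R effective amplitudes/phases, radians).
#' @export
spatial_forward <- function(drive, fields, tissue, K = NULL) {
  if (fields$R < 1) stop("empty ROI")
  if (drive$L != fields$L) stop("drive and fields disagree on channel count")
  if (is.null(K)) K <- default_K(drive$N)
  Z <- effective_z(drive, fields)
  states <- forward_arrs(Z, tissue, K)
  list(echoes = arr_echoes(states), alpha = Mod(Z),
       phi = ifelse(Mod(Z) > 0, Arg(Z), 0))
}

# internal: echoes only
spatial_echoes <- function(drive, fields, tissue, K) {
  Z <- effective_z(drive, fields)
  arr_echoes(forward_arrs(Z, tissue, K))
}

# ASM gradient core for pTx: d_x, d_y are N x L real matrices (implicit
# part). Seeds per voxel; the rotation partials are taken with respect to
# the complex effective pulse (Wirtinger form) and chained through
# z = sum_l conj(B_l) (x_l + i y_l).
asm_core_ptx <- function(drive, fields, tissue, K, kind, target, weights) {
  N <- drive$N
  L <- drive$L
  R <- fields$R
  B <- fields$B
  Z <- effective_z(drive, fields)
  states <- forward_arrs(Z, tissue, K)                     # pass 1
  echoes <- arr_echoes(states)
  d_x <- matrix(0, N, L)
  d_y <- matrix(0, N, L)
  if (is.null(kind))
    return(list(d_x = d_x, d_y = d_y, echoes = echoes))
  w <- switch(kind,
              error = weights * Conj(echoes - target),
              signal = -weights * Conj(echoes))
  w <- matrix(w, N - 1, R)
  ehalf <- relaxation_operator(tissue, interval = tissue$tau / 2)
  regrow <- if (tissue$regrowth && !tissue$relaxation_off)
    (1 - exp(-tissue$tau / 2 / tissue$T1)) else 0
  # backward adjoint recursion                              pass 2
  lams <- vector("list", N)
  Lam <- array(0 + 0i, c(3, K + 1, R))
  Lam[2, 1, ] <- w[N - 1, ]
  lams[[N]] <- Lam
  for (n in seq(N - 2, 0)) {
    re <- rot_entries_z(Z[n + 2, ])
    Lam <- pullback_half_arr(Lam, ehalf)
    Lam <- apply_rot_arr(Lam, re, transpose = TRUE)
    Lam <- pullback_half_arr(Lam, ehalf)
    if (n + 1 >= 2) Lam[2, 1, ] <- Lam[2, 1, ] + w[n, ]
    lams[[n + 1]] <- Lam
  }
  count_pass("backward")
  # derivative products                                     passes 3 + 4
  pair_sums <- function(kap, h, z) {
    wp <- rot_wirtinger_partials(z)
    a <- complex(R)
    b <- complex(R)
    for (i in 1:3) {
      ki <- arr_plane(kap, i)
      for (j in 1:3) {
        G <- colSums(ki * arr_plane(h, j))
        a <- a + wp$Dz[i, j, ] * G
        b <- b + wp$Dzb[i, j, ] * G
      }
    }
    list(a = a, b = b)
  }
  accumulate <- function(n_row, ab) {
    ca <- colSums(Conj(B) * ab$a)
    cb <- colSums(B * ab$b)
    d_x[n_row, ] <<- Re(ca + cb)
    d_y[n_row, ] <<- Re(1i * ca - 1i * cb)
  }
  accumulate(1, pair_sums(lams[[1]], states[[1]], Z[1, ]))
  for (n in seq_len(N - 1)) {
    h <- half_arr(states[[n + 1]], ehalf, regrow)
    kap <- pullback_half_arr(lams[[n + 1]], ehalf)
    accumulate(n + 1, pair_sums(kap, h, Z[n + 1, ]))
  }
  count_pass("derivative", 2L)
  list(d_x = d_x, d_y = d_y, echoes = echoes)
}

# ---------------------------------------------------------------------------
# ROI subsampling
# ---------------------------------------------------------------------------

#' Subsample the ROI of a transmit-field set
#'
#' Mode `"stride"` keeps every `factor`-th voxel along each axis. Mode
#' `"tetrahedral"` keeps an alternating-offset lattice (the stride lattice
#' plus a copy offset by half the stride along every axis), emulating a
#' face-centred sampling of the volume at roughly twice the stride density.
#'
#' @param fields a [transmit_field_set()].
#' @param mode `"stride"` (default) or `"tetrahedral"`.
#' @param factor integer subsampling factor (>= 1).
#' @return the reduced `transmit_field_set`.
#' @export
subsample_roi <- function(fields, mode = c("stride", "tetrahedral"),
                          factor = 1L) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(fields)
  cm <- fields$coords %% factor
  flat <- matrix(rep(fields$dims == 1L, each = nrow(cm)), ncol = 3)
  keep <- if (mode == "stride") {
    rowSums(cm == 0L | flat) == 3L
  } else {
    off <- factor %/% 2L
    (rowSums(cm == 0L | flat) == 3L) | (rowSums(cm == off | flat) == 3L)
  }
  if (!any(keep)) stop("subsampling removed every ROI voxel")
  transmit_field_set(fields$B[keep, , drop = FALSE],
                     fields$coords[keep, , drop = FALSE], fields$dims)
}

# ---------------------------------------------------------------------------
# Synthetic multi-channel transmit maps
# ---------------------------------------------------------------------------

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic multi-channel transmit-field maps
#'
#' Generates complex per-channel sensitivity maps emulating an L-channel
#' head coil at high field strength: channel amplitude envelopes peaked
#' near the channel position on a ring around an elliptical (2D) or
#' ellipsoidal (3D) ROI, a common centre-brightening factor, per-channel
#' azimuthal phase offsets `2 pi l / L`, distance-dependent phase ramps and
#' smooth low-order random phase/amplitude perturbations. The `"uniform"`
#' profile returns `B = 1` for every channel (useful for reduction tests).
#' Deterministic given `(L, grid_shape, profile, seed)`.
#'
#' @param L number of transmit channels.
#' @param grid_shape integer length-2 or length-3 grid shape.
#' @param profile `"headcoil"` (default) or `"uniform"`.
#' @param seed integer seed fixing all randomness.
#' @return a [transmit_field_set()] whose ROI is the elliptical mask.
#' @export
#' @examples
#' fs <- synth_field_maps(8, c(25, 25), seed = 1)
synth_field_maps <- function(L, grid_shape, profile = c("headcoil", "uniform"),
                             seed = 1L) {
  profile <- match.arg(profile)
  grid_shape <- as.integer(grid_shape)
  if (!length(grid_shape) %in% c(2L, 3L)) stop("grid_shape must be 2D or 3D")
  dims <- if (length(grid_shape) == 2L) c(grid_shape, 1L) else grid_shape
  # elliptical / ellipsoidal ROI with semi-axes just inside the grid
  semi <- pmax((dims - 3) / 2, 0.5)
  if (length(grid_shape) == 2L) semi[2] <- 0.92 * semi[2]
  ctr <- (dims - 1) / 2
  g <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                             z = 0:(dims[3] - 1)))
  rel <- sweep(g, 2, ctr)
  inside <- rowSums(sweep(rel, 2, semi, "/")^2) <= 1
  coords <- g[inside, , drop = FALSE]
  relc <- rel[inside, , drop = FALSE]
  R <- nrow(coords)
  if (profile == "uniform")
    return(transmit_field_set(matrix(1 + 0i, R, L), coords, dims))
  rad <- sqrt(sum(semi[1:2]^2) / 2)
  rho <- sqrt(rowSums(sweep(relc, 2, semi, "/")^2)) # 0 centre .. 1 edge
  with_local_seed(seed, {
    B <- matrix(0 + 0i, R, L)
    for (l in seq_len(L)) {
      th <- 2 * pi * (l - 1) / L
      pos <- 1.15 * c(semi[1] * cos(th), semi[2] * sin(th), 0)
      d <- sqrt((relc[, 1] - pos[1])^2 + (relc[, 2] - pos[2])^2 +
                  (0.5 * relc[, 3])^2) / rad
      amp <- (0.35 + 0.65 * exp(-d^2 / (2 * 0.8^2))) *
        (0.80 + 0.40 * exp(-rho^2 / 0.5)) *
        (1 + 0.05 * stats::rnorm(1) * (relc[, 1] / max(semi)) +
           0.05 * stats::rnorm(1) * (relc[, 2] / max(semi)))
      ph <- th - 1.1 * d +
        0.3 * stats::rnorm(1) * (relc[, 1] / max(semi)) +
        0.3 * stats::rnorm(1) * (relc[, 2] / max(semi)) +
        0.15 * stats::rnorm(1) * (relc[, 1] * relc[, 2] / max(semi)^2)
      B[, l] <- amp * exp(1i * ph)
    }
    transmit_field_set(B, coords, dims)
  })
}

#' Circularly-polarized (quadrature) drive for a nominal train
#'
#' Builds the per-channel drive that reproduces a nominal pulse train in
#' quadrature mode: channel l carries the nominal pulse times
#' `exp(2 pi i l / L)`, normalized so that the effective pulse at the
#' calibration voxel (the ROI voxel closest to the grid centre) equals the
#' nominal train exactly.
#'
#' @param train a [pulse_train()] (nominal amplitudes/phases).
#' @param fields a [transmit_field_set()].
#' @return a [channel_drive()].
#' @export
cp_mode_drive <- function(train, fields) {
  L <- fields$L
  modes <- exp(2i * pi * (seq_len(L) - 1) / L)
  ctr <- (fields$dims - 1) / 2
  d2 <- rowSums(sweep(fields$coords, 2, ctr)^2)
  cal <- which.min(d2)
  s0 <- sum(Conj(fields$B[cal, ]) * modes)
  if (Mod(s0) < 1e-9) stop("degenerate quadrature combination at calibration voxel")
  W <- outer(train$alpha * exp(1i * train$phi), modes / s0)
  channel_drive(Re(W), Im(W))
}

# ---------------------------------------------------------------------------
# Field-map I/O (plain-text containers) and echo export
# ---------------------------------------------------------------------------

#' Write / read transmit-field maps as a JSON container
#'
#' The container stores the grid shape, voxel coordinates and per-channel
#' real/imaginary sensitivities. The phase convention is the generator's
#' own (azimuthal channel offsets plus smooth ramps); no transceive-phase
#' correction is implied.
#'
#' @param fields a [transmit_field_set()].
#' @param path file path.
#' @return `write_field_maps` returns `path` invisibly; `read_field_maps`
#'   returns a [transmit_field_set()].
#' @export
write_field_maps <- function(fields, path) {
  payload <- list(format = "epgopt-fieldmaps-v1",
                  dims = fields$dims,
                  coords = fields$coords,
                  B_real = Re(fields$B),
                  B_imag = Im(fields$B))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_field_maps
#' @export
read_field_maps <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "epgopt-fieldmaps-v1"))
    stop("not an epgopt field-map container")
  transmit_field_set(matrix(complex(real = p$B_real, imaginary = p$B_imag),
                            nrow = nrow(p$coords)),
                     p$coords, p$dims)
}

#' Read transmit-field maps from NIfTI magnitude/phase volumes
#'
#' Accepts one magnitude and one phase volume per channel plus a mask
#' volume (all of identical shape); voxels with non-zero mask become the
#' ROI. Phases are in radians. Requires the RNifti package.
#'
#' @param magnitude,phase character vectors of per-channel file paths.
#' @param mask path of the mask volume.
#' @return a [transmit_field_set()].
#' @export
read_field_maps_nifti <- function(magnitude, phase, mask) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI maps requires the RNifti package")
  if (length(magnitude) != length(phase))
    stop("need one magnitude and one phase volume per channel")
  mk <- as.array(RNifti::readNifti(mask))
  dims <- dim(mk)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  idx <- which(mk != 0, arr.ind = TRUE)
  if (ncol(idx) == 2L) idx <- cbind(idx, 1L)
  B <- sapply(seq_along(magnitude), function(l) {
    m <- as.array(RNifti::readNifti(magnitude[l]))
    p <- as.array(RNifti::readNifti(phase[l]))
    m[mk != 0] * exp(1i * p[mk != 0])
  })
  transmit_field_set(as.matrix(B), idx - 1L, dims)
}

#' Export per-voxel echo amplitudes as CSV
#'
#' @param echoes complex (N-1) x R echo matrix (from [spatial_forward()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_echoes_csv <- function(echoes, path) {
  echoes <- as.matrix(echoes)
  df <- data.frame(echo_index = rep(seq_len(nrow(echoes)), ncol(echoes)),
                   voxel = rep(seq_len(ncol(echoes)), each = nrow(echoes)),
                   amplitude = as.vector(Mod(echoes)),
                   phase_deg = as.vector(wrap_deg(rad2deg(Arg(echoes)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
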