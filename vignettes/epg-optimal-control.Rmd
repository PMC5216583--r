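---
title: "Designing turbo spin-echo flip-angle trains by optimal control of the extended phase graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing turbo spin-echo flip-angle trains by optimal control of the extended phase graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgopt)
```

## The model

A multi spin-echo (turbo spin-echo, TSE) sequence applies an excitation
pulse followed by a train of refocusing pulses with flip angles
$\alpha_n$ and phases $\phi_n$, one echo per refocusing period. `epgopt`
models the magnetization with the extended phase graph (EPG): the
transverse and longitudinal magnetization are expanded in Fourier
coefficients — configuration states $(F_k^+, F_k^-, Z_k)$ — with respect
to the intra-voxel gradient-dephasing angle. Three operators generate the
dynamics:

* the **rotation** $R(\alpha, \phi)$, a $3\times 3$ complex block applied
  identically to every order $k$;
* the **relaxation** $E(t) = \mathrm{diag}(e^{-t/T_2}, e^{-t/T_2},
  e^{-t/T_1})$;
* the **shift** $S$, which advances every transverse order by one
  ($F(k) \mapsto F(k+1)$) and leaves $Z_k$ untouched.

Stacking the states up to a maximum order $K$ into a vector $f_n$ of
length $3(K+1)$ turns one period into a linear map, $f_{n+1} = P_n f_n$,
with $f_0$ the equilibrium state ($Z_0 = 1$) — a discrete-time dynamical
system whose inputs are the pulse parameters. The echo at time index $n$
is the $F_0^-$ component of $f_n$ for $n \ge 2$; echo amplitudes are
fractions of the equilibrium magnetization $M_0 = 1$.

### Timing convention

Within each refocusing period the package applies
*half-period decay + one dephasing unit*, the rotation, then
*half-period decay + one dephasing unit*:
$f_{n+1} = (S E(\tau/2))\, R(\alpha_n, \phi_n)\, (S E(\tau/2))\, f_n$.
This is the CPMG timing — the excitation-to-first-pulse interval is
$\tau/2$ — and it places every echo exactly at configuration order zero.
$E$ and $S$ commute, so the order within a half period is immaterial.
Because each period applies two dephasing units, a trajectory of $N$
pulses can populate orders up to $2(N-1)$; the default truncation
$K = \min(N, 25)$ silently discards higher orders. That truncation is an
approximation (high orders carry little signal for long trains) and can
be overridden everywhere.

Relaxation is pure decay by default: the equilibrium-recovery term
$(1 - e^{-t/T_1}) M_0$ is *not* added to $Z_0$ unless
`tissue_params(..., regrowth = TRUE)` asks for it. Under the CPMG timing,
regrown longitudinal magnetization converted by a refocusing pulse
rephases at the pulse times, not the echo centres, so the sampled echo
trains are identical either way; the opt-in flag matters only if states
are inspected directly. No preset uses it.

### Parallel transmit

An $L$-channel transmit system superposes per-channel fields. With
complex channel sensitivities $B_\ell(r)$ and Cartesian drive weights
$(x_{n,\ell}, y_{n,\ell})$, the pulse seen by voxel $r$ is
$z_{n,r} = \sum_\ell B_\ell(r)^{*} (x_{n,\ell} + i\, y_{n,\ell})$, with
effective amplitude $|z|$ and phase $\arg z$. The EPG then runs per
voxel over the region of interest (ROI); `epgopt` vectorizes the
recursion across voxels.

## Design problems

A design problem minimizes a smooth objective under smooth inequality
constraints. The building blocks, each available in single-channel and
spatially resolved (pTx) form:

| block | form |
|---|---|
| target error | $\tfrac12 \sum_r \sum_n c_n \lvert s_{n,r} - t_n \rvert^2$ |
| signal amplitude | $-\tfrac12 \sum_r \sum_n c_n \lvert s_{n,r} \rvert^2$ |
| total RF power | $\tfrac12 \sum_n \alpha_n^2$ or $\tfrac12 \sum_{n,\ell} (x_{n,\ell}^2 + y_{n,\ell}^2)$ |
| peak RF power | $\alpha_n \le \alpha_{\max}$ or $x_{n,\ell}^2 + y_{n,\ell}^2 \le \alpha_{\max}^2$ |

The per-echo weights $c_n$ default to 1; zero weights mask echoes (e.g.
to ignore the approach to the pseudo steady state) and larger weights
emphasize central k-space echoes. Targets $t_n$ specify only the echo
component; a convenient idiom is `epg_of_train()`, which uses the ideal
(homogeneous-field) response of a published reference train as the
target. The signal-amplitude row is stated with its minus sign because
maximization is implemented as minimization of the negative; total power
is kept positive, consistent with its derivative $\partial s / \partial
\alpha_j = \alpha_j$.

**Grouping.** Piecewise-constant trains are expressed as $\alpha = Q a$,
$\phi = Q b$ with $Q$ the binary incidence matrix of an ordered partition
of the pulse indices (`build_grouping()`); gradients project back as
$\partial s/\partial a = (\partial s/\partial \alpha) Q$. A standard
design with $G$ groups has $2G$ real parameters, a pTx design $2GL$.

## Exact gradients: the adjoint-state method

Derivatives of the quadratic objectives with respect to every pulse
parameter are computed exactly by a forward/backward recursion: one
forward pass stores the trajectory; the backward recursion
$\lambda_{N-1} = (f_N - t_N)^H C_N$,
$\lambda_n = \lambda_{n+1} P_{n+1} + (f_{n+1} - t_{n+1})^H C_{n+1}$
accumulates the adjoint covectors; the derivative products
$\partial s/\partial \alpha_n = \lambda_n (\partial P_n / \partial
\alpha_n) f_n$ are assembled in one combined loop costing about two more
passes. Four EPG-equivalent passes in total, independent of the number of
design parameters — against $2 N_p + 1$ simulations for central
differencing (`gradient_fd_oracle()`, which serves as the test oracle for
every gradient in the package).

Two implementation points deserve note:

* **The shift is real-linear, not complex-linear.** In the half-ladder
  storage, the vacated $F_0^+$ slot is refilled with
  $\overline{F_1^-}$. The adjoint recursion is therefore carried out over
  the real field: covectors act as $v \mapsto \mathrm{Re}(\lambda v)$,
  and the pullback through the shift deposits the *conjugate* of the
  $F_0^+$ covector entry into the $F_1^-$ slot. All reported gradients
  are exactly real.
* **pTx derivatives are taken in Cartesian form.** The rotation block is
  written as a smooth function of the complex effective pulse $z$ (its
  entries involve $\sin^2(|z|/2)/|z|^2$ and $\sin|z|/|z|$, both analytic
  in $(z, \bar z)$), and the chain rule runs through
  $\partial z/\partial x_{n,\ell} = B_\ell^*$. This avoids the phase
  singularity of the $(\alpha, \phi)$ parametrization at zero effective
  amplitude, which matters for solver robustness whenever channels
  cancel. Near $|z| < 10^{-4}$ the quotients switch to series
  expansions with $O(|z|^4)$ error.

The rotation-block partials themselves are obtained by entrywise
differentiation of the closed-form block and validated against central
finite differences; the finite-difference step defaults to $10^{-6}$ rad
(complex-step differentiation is not available since the operators are
already complex).

## The solver

`solve_design()` minimizes over the packed free parameters with exact
gradients throughout:

* amplitude non-negativity (which removes the
  $\alpha \leftrightarrow -\alpha$, $\phi \leftrightarrow \phi + \pi$
  ambiguity) and standard-mode peak caps are *box bounds*, handled
  natively by the limited-memory BFGS inner solver (`optim`'s L-BFGS-B,
  `lmm = 40` correction pairs by default);
* the remaining inequality constraints — total power, target error, pTx
  per-channel peak power — enter an augmented-Lagrangian outer loop with
  multiplier updates and penalty growth when feasibility stalls.

Nonlinear constraints are tightened internally by the feasibility margin
(`constraint_tolerance`, default $10^{-9}$), so converged solutions are
strictly feasible for the true constraints — the behaviour an
interior-point method gives for free. This matters when a constraint is
active at the optimum: the minimum-power constant-intensity design ends
with target error just *below* $\sigma^2$ rather than floating-point
above it.

`max_iterations` caps the total number of inner gradient evaluations
across all outer rounds (default 200; the pTx presets halt at 50, and the
standard presets use larger budgets — 2000 for the signal-maximization
preset, 1500 for the constant-intensity one — because no stopping rule is
inherent to those problems and the budgets are cheap at these sizes).
Everything is deterministic: the only seeded component in the package is
the synthetic field-map generator.

## Preset experiments

* `test1_max_signal` — unconstrained signal maximization, $N = 60$,
  $(T_1, T_2) = (1000, 150)$ ms, starting from $90^\circ/60^\circ$ under
  CPMG phases. Recovers the classical $90^\circ/180^\circ$ train.
* `test2_constant_intensity` — minimum total power subject to a constant
  echo train $I_c \in \{0.3, 0.6, 0.9\}$ within $\sigma = 10^{-3}$,
  relaxation off, $N = 50$, refocusing start $18^\circ$. The preset fixes
  the excitation at $90^\circ$ and the phases at CPMG and optimizes the
  refocusing amplitudes — the configuration in which the analytic
  constant-intensity solution exists; the target is $i\,I_c$ because
  echoes lie on the $+i$ axis under this phase convention. $N = 50$ is a
  package choice (the experiment's length is not prescribed); the
  $\sigma$ criterion is independent of it.
* `test3_capped_60` — signal maximization of echoes 6+ with refocusing
  amplitudes capped at $60^\circ$ and all refocusing pulses sharing one
  (amplitude, phase) pair. The expected optimum is the cap with a
  $90^\circ$ excitation-to-refocusing phase offset, i.e. the CPMG
  condition emerges from the optimization. One subtlety: starting with
  *all* phases zero is an exact stationary point — the objective is
  invariant under global phase reflection
  ($R(\alpha,-\phi) = \overline{R(\alpha,\phi)}$ conjugates the whole
  trajectory and echo magnitudes are unchanged), so the phase gradient
  vanishes identically on the symmetric manifold and no exact-gradient
  method can leave it. The preset therefore starts the refocusing phase
  at $10^\circ$; any small nonzero offset flows to $\pm 90^\circ$, and
  the reported offset $|\phi_{\mathrm{ref}} - \phi_{\mathrm{exc}}|$
  wrapped to $[0^\circ, 180^\circ]$ is the same in both basins. A
  time-varying variant (`test3_time_varying`) frees every refocusing
  pulse individually.
* `test4_ptx3d_synthetic` / `test5_ptx2d_synthetic` — eight-channel pTx
  signal homogenization: the target is the ideal EPG response of a
  published pseudo-steady-state train
  ($(90, 151, 90, 67, 60 \times 48)^\circ$ at $\tau = 2.9$ ms for the 3D
  phantom-like case, $(105, 174, 145, 140 \times 7)^\circ$ at
  $\tau = 12$ ms with white-matter $(T_1, T_2) = (1500, 100)$ ms for the
  2D head-like case), the start is that train in quadrature (circularly
  polarized) mode, per-channel nominal amplitudes are bounded by
  $270^\circ$, total power by twice the quadrature drive's, and the
  solver halts after 50 iterations. The 3D preset groups pulses 23–52
  (1-based 23..52) into three blocks of ten, giving
  $(22 + 3) \times 8 \times 2 = 400$ parameters. The central k-space
  echo (echo 5) carries weight 2 in the 2D preset.

Tests 1–3 are free of any synthetic input and reproduce printed optima.
Echo spacing is not printed for them; the presets use $\tau = 10$ ms, a
typical TSE spacing, and the recovered optima do not depend on it.

## The synthetic transmit maps

Measured multi-channel $B_1^+$ maps are exam-specific, so the pTx presets
run on `synth_field_maps()`, which emulates an eight-channel head coil at
high field: per-channel amplitude envelopes peaked near channel positions
on a ring around an elliptical (2D) or ellipsoidal (3D) ROI, a common
centre-brightening factor, azimuthal phase offsets $2\pi\ell/L$,
distance-dependent phase ramps and smooth low-order seeded
perturbations. The 2D default grid ($51 \times 51$, stride-4
subsampling) yields about a hundred ROI voxels and the 3D default
($25^3$, alternating-offset "tetrahedral" lattice, factor 5) about
eighty — the scale of the measured-map experiments they stand in for.
The quadrature combination of the generated maps has a coefficient of
variation above 0.1 over the ROI, so there is genuine inhomogeneity to
correct, and the homogenization presets reduce the per-echo relative
standard deviation across voxels for (in practice all) echoes.

What the synthetic maps do *not* emulate: measured transceive-phase
structure, tissue-dependent wave effects, map noise, or masking derived
from anatomy. Passing the homogenization tests therefore demonstrates
the correctness and effectiveness of the design machinery on realistic
inhomogeneity scales, not performance on any particular scanner or
subject.

## Numerical choices and degenerate inputs

* Angles are radians internally, degrees at every user interface;
  reported phases are wrapped to $[-180^\circ, 180^\circ)$.
* $K = \min(N, 25)$ by default, always overridable; states beyond $K$
  are silently dropped.
* Zero-amplitude pulses are valid everywhere ($\phi$ is reported as 0 by
  convention at $\alpha = 0$; gradients use the Cartesian form).
* `tissue_params()` warns on $T_2 > T_1$ but proceeds; non-positive
  times are errors.
* The ROI subsampler provides both a plain stride and the
  alternating-offset (face-centred-like) lattice; the choice affects
  conditioning of the spatial problem, not correctness. Axes of extent 1
  are exempt from the lattice conditions so 2D grids subsample in-plane.
* Field maps travel in a plain-text JSON container
  (`write_field_maps()`); NIfTI magnitude/phase volumes are read via
  `read_field_maps_nifti()` when the RNifti package is available.

## Known limitations

* Fixed echo spacing: derivatives with respect to $\tau$, $T_1$, $T_2$
  are not implemented (the same adjoint machinery would extend to them).
* No diffusion, flow, or gradient-waveform effects in the EPG.
* No specific-absorption-rate models beyond total and peak nominal RF
  power.
* The solver finds local minima; no multi-start machinery is provided.
  For the presets this is what is wanted — the recovered optima are the
  analytically known ones.
* Truncation at $K$ is an approximation for long trains; the
  truncation-equivalence tests quantify it only for short trains where
  the full ladder fits.
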