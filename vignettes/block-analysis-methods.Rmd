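---
title: "Spatial block analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial block analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockfluct)
```

## The problem

A molecular simulation is a closed box: a fixed number of particles
$N_0$ in a periodic cube of edge $L_0$.  Bulk response functions such as
the isothermal compressibility $\kappa_T$ are, however, defined through
*grand-canonical* fluctuations — the variance of the particle number in
an open volume:
$$
\chi_T^\infty \;=\; \frac{\langle N^2\rangle - \langle N\rangle^2}
                         {\langle N\rangle}
          \;=\; \rho\, k_BT\, \kappa_T ,
$$
which equals 1 for an ideal gas.  Measuring this ratio naively inside a
closed simulation gives a systematically wrong answer: at the scale of
the whole box the particle number cannot fluctuate at all.

Spatial block analysis (SBA) turns this obstacle into a method.  Cubic
blocks of edge $L = \lambda L_0$, $0 < \lambda \le 1$, are placed at
random positions in the box (wrapping across the periodic boundary), and
the particle-number fluctuation ratio $\chi_T(\lambda)$ is measured as a
function of block size.  Two finite-size effects shape the curve:

* the **ensemble effect** — a block of relative volume $\lambda^3$ inside
  a closed box sees its fluctuations suppressed by exactly
  $(1-\lambda^3)$; for the ideal gas the block count is binomial
  $(N_0, \lambda^3)$ and the suppression is the entire story,
  $\chi_T(\lambda) = 1 - \lambda^3$;
* the **boundary effect** — pair correlations cut by the block surface
  contribute a surface-to-volume term $\propto 1/L$, with an intensive
  coefficient $c$.

Combining both and multiplying by $\lambda$ gives the working model
$$
\lambda \chi_T(\lambda) \;=\;
  \lambda\,\chi_T^\infty\,(1-\lambda^3) \;+\; \frac{c}{L_0},
$$
linear in $\lambda$ for $\lambda^3 \ll 1$: the slope is the
thermodynamic-limit value $\chi_T^\infty$ and the intercept is $c/L_0$.
A linear regression in a small-$\lambda$ window therefore extrapolates a
*single* simulation to the thermodynamic limit.

Near a critical point the correlation length $\zeta$ is no longer small
against the block size and the next boundary order matters.  The
extended model adds one dimensionless term $b_2/\lambda$ (with
$b_2 = c_2/L_0^2$ kept as a single fitted constant):
$$
\lambda \chi_T(\lambda) \;=\;
  \lambda\,\chi_T^\infty\,(1-\lambda^3) + \frac{c_1}{L_0}
  + \frac{b_2}{\lambda}.
$$

For mixtures the same logic applies to finite-size Kirkwood–Buff
integrals (KBIs).  The block estimator
$$
G_{ij}(\lambda) = V\,
  \frac{\langle N_iN_j\rangle - \langle N_i\rangle\langle N_j\rangle}
       {\langle N_i\rangle \langle N_j\rangle}
  - \delta_{ij}\frac{V}{\langle N_i\rangle},
\qquad V = (\lambda L_0)^3,
$$
obeys
$$
\lambda G_{ij}(\lambda) \;=\;
  \lambda\,G_{ij}^\infty\,(1-\lambda^3)
  - \lambda^4 \frac{\delta_{ij}}{\rho_i}
  + \frac{\alpha_{ij}}{L_0},
$$
so after subtracting the known $-\lambda^4\delta_{ij}/\rho_i$ piece the
fit is again a two-parameter linear regression.  The extrapolated
$G_{ij}^\infty$ feed the standard KB closures for the mixture
compressibility and for $\partial\mu_A/\partial\rho_A$, whose
integration over a state-point scan yields chemical-potential
differences; subtracting $k_BT\ln\rho$ (and $k_BT\ln x_A$ for mixtures)
gives the excess chemical potential up to an additive constant fixed by
one externally supplied reference value.

## Estimators and their uncertainties

`fluctuation_curve()` and `kbi_curve()` pool block-count moments over
all (frame, block) samples of each $\lambda$ — matching the definition
of a single count distribution $P_{L,L_0}(N)$ — rather than averaging
per-frame ratios.  Standard errors come from a frame-level delete-one
jackknife of the pooled ratio: blocks within a frame are strongly
correlated (they sample the same configuration), frames are treated as
approximately independent.  Two exact identities are preserved by
construction and asserted in the tests:

* at $\lambda = 1$ the whole-box count of a closed trajectory never
  fluctuates, so $\chi_T(1) = 0$ and $G_{ii}(1) = -1/\rho_i$ *exactly*
  (note the sign: the zero-fluctuation limit of the estimator is
  $-1/\rho_i$; plotting conventions that display $+1/\rho_i$ differ only
  by sign);
* $G_{AB} = G_{BA}$ exactly, because one pooled $\langle N_AN_B\rangle$
  sample set serves both orderings.

Block membership is half-open per axis ($[o, o+L)$ after periodic
unwrapping), so tiling blocks never double-count a particle; origins are
uniform over the box and blocks may straddle the boundary.
`exhaustive_block_counts()` provides the deterministic regular-grid
counterpart used to validate the random-origin estimator on frozen
configurations.

## Fit-window policy

The scaling models hold for $\zeta < L < L_0$.  Two guards implement
this:

* the default $\lambda$ grid floors the block edge at $1\,\sigma$
  (single component) or $2\,\sigma$ (mixtures);
* the default fit window is $[\max(2\sigma/L_0,\ \zeta_g/L_0),\ 0.3]$,
  where $\zeta_g$ is a user-supplied correlation-length guard
  (`zeta_guard`, default 0).  The correlation length is *never*
  estimated automatically; in a dense liquid the radial distribution
  function (see `radial_distribution()`) decays within a few $\sigma$,
  and blocks smaller than $\sim 2\,\sigma$ sit inside the
  packing-structure regime where the $1/L$ expansion is not yet valid —
  including them visibly biases the slope upward in small boxes.

The upper edge $0.3$ keeps $\lambda^3 \le 0.027$; the regressor
nevertheless retains the full $\lambda(1-\lambda^3)$ factor, for two
reasons: noiseless model curves are then recovered *exactly* (a sharp
test of the fitting code), and the two-term fit is algebraically the
$b_2 = 0$ restriction of the three-term fit.  In the window the
difference from a pure-$\lambda$ regressor is far below the sampling
noise of any real curve.

Weights are $1/\mathrm{stderr}^2$ when the curve carries finite positive
uncertainties, ordinary least squares otherwise; parameter uncertainties
come from the regression covariance.  A singular or near-singular design
(condition number $>10^{10}$) is an error; a condition number above
$10^6$ warns.

## The synthetic-data oracles

The package ships its own ground truth:

* `generate_ideal_gas()` / `generate_ideal_binary()` place particles
  i.i.d. uniformly, making every downstream estimator exactly solvable:
  $\chi_T(\lambda) = 1-\lambda^3$, $G_{AB} = 0$,
  $G_{AA} = -\lambda^3/\rho_A$.  An ideal-gas "trajectory" is a list of
  independent frames — statistically equivalent to simulating
  non-interacting particles and much cheaper.
* `generate_synthetic_curve()` draws $\lambda\chi(\lambda)$ from the
  extended finite-size model plus i.i.d. Gaussian noise of known
  standard deviation, recording the ground-truth parameters in the curve
  metadata for recovery tests.

What these fixtures do *not* emulate: temporal correlation between
frames, non-Gaussian and $\lambda$-correlated sampling noise of real
block counts, packing structure at $L \lesssim 2\sigma$, and the
implicit periodic-image anisotropy that produces oscillations near
$\lambda \approx 1$ in small boxes.  Passing the synthetic suites
therefore validates the estimator algebra and the fitting machinery, not
the physics of any particular liquid; the MD-based checks cover the
latter at reduced scale.

## The molecular dynamics engine

A deliberately minimal NVT engine for truncated-and-shifted 12-6
Lennard–Jones (TSLJ) fluids supplies in-package trajectories:

* **Potential.**  $4\epsilon_{ij}[(\sigma_{ij}/r)^{12} -
  (\sigma_{ij}/r)^6] - U_{LJ}(r_c)$ for $r < r_c$, exactly zero beyond.
  The shift makes $U(r_c) = 0$; the force keeps its truncation
  discontinuity — the stated potential *is* the model, and no smoothing
  is applied.  $r_c = 2^{1/6}\sigma$ puts the cutoff at the minimum,
  giving a purely repulsive (WCA-like) fluid.
* **Integrator.**  Velocity Verlet with the Langevin thermostat in a
  BAOAB splitting.  The splitting choice is a pragmatic default (only
  "Langevin thermostat" is canonical here); BAOAB was chosen because at
  $\gamma = 0$ it reduces *exactly* to velocity Verlet, so the
  integrator is testable through energy conservation (drift
  $< 10^{-4}\,\epsilon$/particle over $10^3$ steps at
  $\delta t = 10^{-3}$).
* **Defaults.**  $\delta t = 10^{-3}$, $\gamma = 1$, $m = 1$ for all
  species, in reduced LJ units throughout.
* **Neighbour search.**  A linked-cell list rebuilt every step (cells no
  smaller than $r_c$; brute force below three cells per dimension) —
  simplicity over speed, with correctness guarded by an $O(N^2)$
  minimum-image oracle test at $10^{-10}$ tolerance.
* **Initialisation.**  Perturbed simple cubic lattice at the target
  density; species labels shuffled over sites so mixtures start mixed.
* **Randomness.**  The integrator uses its own counter-seeded PCG32
  stream: trajectories are bit-identical for a given seed regardless of
  the caller's R RNG state.  Every stochastic operation in the package
  takes a mandatory explicit seed.
* **Pressure.**  Virial estimator $P = \rho k_BT + W/(3V_0)$; fixed
  target pressures are realised by `tune_density_to_pressure()`
  (bracketing plus bisection on short NVT runs), the NVT replacement for
  a barostat.  A zero tolerance is rejected: pressure estimates are
  stochastic.

## Numerical choices in the thermodynamic layer

Chemical-potential integration interpolates tabulated $\kappa_T(\rho)$
(or $G_{ij}(\rho_A)$) with a *monotone* piecewise cubic before composite
trapezoid quadrature on a refined grid (64 subintervals per tabulated
interval by default).  Monotone tables get the Hyman-filtered spline
(fourth-order accurate on smooth data — on a 100-point ideal-gas table
the quadrature reproduces $k_BT\ln(\rho/\rho_0)$ to better than
$10^{-7}\,\epsilon$); non-monotone tables, e.g. a near-critical
compressibility cusp, fall back to Fritsch–Carlson monotone Hermite
interpolation, which is shape-preserving for arbitrary data but an order
less accurate.  Ordinary splines were rejected because oscillation in
$\kappa_T$ is amplified by the $1/(\rho^2\kappa_T)$ integrand.

The reference state contributes zero exactly when it coincides with a
grid point of the quadrature (it is always inserted into the refined
grid).  Per-point $\kappa_T$ uncertainties propagate to the integral to
first order assuming independence across state points, each typically
coming from an independent simulation.  Absolute chemical potentials are
out of scope by design: anchoring an excess curve requires one
externally computed reference value (`excess_mu(reference_axis=,
reference_mu=)`), e.g. from a thermodynamic-integration method, and the
curve then passes through it exactly.

"Excess" follows the common usage — strictly the quantity is the
*residual* chemical potential, $\mu$ minus the ideal-gas value at the
same density, temperature and composition.

## Scaled-down study conditions

The reference experiments behind the test suite and the acceptance
script run at desk scale:

* **Reference fluid** ($r_c = 2^{1/6}\sigma$, $\rho\sigma^3 = 0.864$,
  $k_BT = 1.2\,\epsilon$): $N_0 = 2000$–$4000$ with
  $2.5\times10^5$–$3\times10^5$ production steps and 100 random blocks
  per frame, against the production-scale original ($N_0 = 10^5$,
  $10^6$ steps).  The box edge is then $L_0 \approx 13$–$17\,\sigma$
  instead of $\approx 49\,\sigma$, which widens the relative sampling
  error of the extrapolated $\chi_T^\infty$ to roughly 10–15% and makes
  the $2\sigma$ window floor essential; the boundary constant
  $c$, being intensive, is recovered more robustly.
* **Mixture checks** run the pure-A consistency identity (the
  single-component limit of the KB compressibility closure must agree
  with the fluctuation route on the same trajectory) rather than the
  full pressure-tuned composition scan, which needs cluster-scale runs.
* **Near-critical behaviour** (the $1/\lambda$ term) is demonstrated on
  synthetic extended-model curves; resolving it from MD requires the
  original $N_0 = 24{,}000$ systems.

## Known limitations

* Cubic boxes and cubic blocks only; no triclinic cells, no non-cubic
  subdomains.
* No long-range tail corrections (the potentials are short-ranged by
  construction) and no bonded interactions.
* The KBI route assumes the species pair densities are those of the
  closed box; strongly asymmetric or demixing mixtures will hit the
  pole guard in `dmuA_drhoA()`.
* The jackknife treats frames as independent; for strides much shorter
  than the decorrelation time the reported standard errors are
  optimistic.
* Implicit periodic-image anisotropy near $\lambda \approx 1$ is not
  modelled; it is visible in small boxes but lies far outside the fit
  window.

## A worked example

```{r example, eval = FALSE}
library(blockfluct)

# 1. simulate the purely repulsive reference fluid at desk scale
ff   <- lj_force_field(cutoff = 2^(1 / 6))
init <- lattice_configuration(2000, density = 0.864, seed = 42)
prot <- simulation_protocol(temperature = 1.2, friction = 1,
                            n_equilibration_steps = 25000,
                            n_production_steps = 250000,
                            frame_stride = 250, seed = 42)
traj <- run_nvt(init, ff, prot)

# 2. block-fluctuation curve and small-window extrapolation
curve <- fluctuation_curve(traj, n_blocks_per_frame = 100, seed = 43)
fit   <- fit_chi_linear(curve)
fit$parameters          # chi_inf, c

# 3. bulk compressibility
kappa_from_chi(fit$parameters[["chi_inf"]], rho = 0.864, kT = 1.2)
```
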