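---
title: "Phase transitions in dynamically linked particle systems: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase transitions in dynamically linked particle systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

netphase implements a three-tier description of particles that interact
through a dynamical network of elastic links, and the analysis that predicts
when and how the uniform particle distribution destabilizes into aggregates.
This vignette records the models, the discretizations, and — most
importantly — the numerical and design decisions a maintainer would want to
know the reasons for.

## The three tiers

**Agent-based tier.** `N` point particles live on the periodic interval
`[-L, L)`. Unlinked pairs closer than a detection radius `R` become linked
at rate `nu_f / ((N-1) eps^2)` per pair, and each existing link breaks at
rate `nu_d / eps^2`; a link between particles at distance `r` stores the
spring energy `(kappa/2) (r - ell)^2` with rest length `ell < R`. Between
linking events particles follow overdamped (inertia-free) dynamics: drift
down the gradient of the total link energy plus Brownian noise of intensity
`D`. The parameter `eps` measures the scale separation between link
turnover and particle motion. The per-pair creation rate carries the
`1/(N-1)` factor so that the total linking activity per particle stays
bounded as `N` grows; together with the per-link destruction rate `nu_d`
this makes the stationary probability that a given admissible pair is
linked equal to `nu_f / (nu_f + nu_d (N-1))`, the two-state Markov balance
that the test suite checks directly. (The companion per-pair/per-link rate
convention is also the only one consistent with the kinetic closure below;
see "Link turnover rates" under Numerical choices.)

In the `eps = 0` limit links equilibrate instantaneously and the explicit
link set disappears: every pair within `R` interacts, weighted by the
stationary linkage probability. `run_micro()` simulates both variants with
an Euler–Maruyama scheme and an adaptive step (`adaptive_dt()`): the step
is capped by `dt_max`, by a maximal deterministic displacement
`delta_step = 0.1`, and — for `eps > 0` — by `0.1 eps^2 / max(nu_f, nu_d)`
so that per-event probabilities stay below `1 - exp(-0.1)` per step.

**Macroscopic tier.** In the fast-relinking regime the particle density
follows the aggregation–diffusion equation

$$\partial_t f = D\,\Delta f + \nabla\cdot\big(f\, \nabla V * f\big),$$

where the effective pair potential (for the scaled spring constant
`kappa = 2`)

$$V(x) = \big[(|x|-\ell)^2 - (R-\ell)^2\big]\,\chi_{|x|\le R}$$

is a spring well shifted to vanish continuously at the edge of its compact
support. The two-particle link density is slaved to `f` by the closure
`g(x,y) = nu_f/(2 xi nu_d) f(x) f(y) chi_{|x-y|<=R}` (`link_density()`).

**Spectral tier.** Linearizing around the uniform state and expanding in
box modes `exp(i pi k x / L)` decouples the modes with growth rates
`lambda_k = -(pi^2 |k|^2 / L^2)(D + Vhat_k)`. All stability questions
reduce to the Fourier coefficients of `V`: in 1D a closed trigonometric
form (`potential_mode_1d()`), in 2D a Bessel–Struve expression
(`potential_mode_2d()`, with `struve_h()` summing the defining series of
the Struve function, which no installed package provides; the series is
benign for the small arguments that arise, and a coarser truncation of the
same series acts as the test oracle, cross-checked once against scipy).

## Thresholds and bifurcation type

The uniform state destabilizes through the first mode when `D` drops below
`D_c = -Vhat_1` (`critical_noise()`). Because `Vhat_1` is affine in `ell`
at fixed geometry, the instability boundary is the line
`D = 0.1781 (0.4947 - ell)` for the reference geometry `R = 0.75, L = 3`;
`ell_c = R alpha_c ≈ 0.4947` is the rest length beyond which the potential
can no longer aggregate at any noise level. (Printed references often
carry `0.4948`; the exact closed form `0.75 (4-pi)(sqrt(2)+1)/pi =
0.494743` rounds to `0.4947`, and `critical_lengths_1d()` reports the
exact value.)

The *type* of transition comes from the weakly nonlinear expansion of the
critical mode. In 1D the cubic coefficient is proportional to
`Vhat_1 (2 Vhat_2 - Vhat_1)`, so the sign of `2 Vhat_2 - Vhat_1` alone
decides: supercritical (continuous onset of the aggregated branch) for
`ell` in `(0.4530, 0.4947)`, subcritical (discontinuous, with bistability)
below `0.4530` (`bifurcation_type_1d()`, `critical_lengths_1d()`).

On the square box the two critical modes `(1,0)` and `(0,1)` couple
through the `(1,1)` harmonic and the criterion involves `D`; evaluated at
the crossing it reduces to the sign of the discriminant `V*`
(`vstar_discriminant()`). For `R/L = 1` this yields a genuine
supercritical window `alpha` in `(0.1016, 0.5818)`.

Two numerical subtleties here deserve record:

* **Degenerate collar below `alpha_c`.** As `alpha` approaches `alpha_c`
  every factor of `V*` vanishes, and exact evaluation finds sign
  excursions of depth `1e-7` and smaller (versus `0.23` inside the genuine
  `R/L = 1` window) for `R/L = 1/2` and `1/4`. At that depth the quartic
  terms dropped by the weakly nonlinear expansion dominate, so the
  expansion cannot classify the bifurcation there.
  `supercritical_window_2d()` therefore filters sign intervals whose depth
  is below `rel_depth = 1e-4` of the scan maximum, reporting these
  geometries as subcritical-only — the physically meaningful statement.
* **Saturation factor of the amplitude prediction.** The literal
  expansion saturates the critical amplitude with the factor
  `2 lambda - lambda_2`; near threshold `|lambda_2| >> lambda` and the
  leading form `-lambda_2` is equivalent at the order retained. The
  reference amplitude tables follow the leading form (the literal factor
  shifts `|A|` by ~10% at `lambda = 1e-3`), so
  `amplitude_prediction(saturation = "leading")` is the default and
  `"full"` keeps the literal factor. The derived perturbation estimate
  `|rho|_th = 2|A| + lambda L / (pi^2 (2 Vhat_2 - Vhat_1))` is an upper
  estimate, not an error-modelled prediction. Note also that `|A|` scales
  as `C sqrt(lambda)` with `C ≈ 3.5` for `ell = 0.4725`: it is the initial
  perturbation `delta <= sqrt(lambda)` that must be small, not `|A|`
  itself.

## The finite-volume solvers

The macroscopic equation is a gradient flow of the free energy
`E[f] = ∫ (D f log f + f (V*f) / 2)`, and steady states are exactly the
densities with constant `xi = D log f + V*f`. The solver discretizes the
equivalent form `∂_t f = ∇·(f ∇xi)` with cell-centred finite volumes:
edge velocity `u = -Δxi/dx`, upwind edge flux `u⁺ f_left + u⁻ f_right`,
forward Euler in time. This is the standard positivity-preserving,
well-balanced, energy-decaying construction for aggregation–diffusion
equations: constant `xi` gives *exactly* zero flux (the uniform state is a
machine-precision fixed point, and converged states are genuine discrete
steady states), fluxes telescope (mass conserved to roundoff), and under
the step-size bounds `dt <= 0.4 dx / max|u|` and `dt <= 0.2 dx^2 / D`
(per dimension) the update keeps `f > 0`; the free energy is monitored and
decays along every trajectory the tests run. Convergence is declared when
the steady-state residual `xi* = max_x |xi - mean(xi)| < 1e-7`, recorded
on a geometric time grid to mirror the `log10 t` residual plots.

The interaction term uses the kernel sampled at cell-centre minimum-image
distances; the convolution is a direct compact-support sum in 1D and a
circular FFT product in 2D (exact for the sampled kernel; the DFT of the
sampled kernel at mode `(1,0)` reproduces the Bessel–Struve coefficient to
1% at 128 cells and to `1e-6` relative at 64 cells for `R/L = 1`).

**Resolution matters near threshold.** The discrete kernel shifts the
effective instability threshold by the sampling error of `Vhat_1`
(about `2e-4` in `D` at 64 cells, `<5e-5` at 128); sweeps that probe
`|lambda| <= 5e-4` therefore use 128–256 cells. The default 1D production
resolution is 256 cells, where the steady perturbation amplitude at
`lambda = 1e-3` changes by less than 1% on further refinement to 512.

**2D runs and symmetry.** The reference initial datum perturbs only the
`x` cosine. A deterministic solver then preserves `y`-invariance exactly
and can only ever produce stripes — but the 2D bifurcation type lives in
the coupling to the `(1,1)` mode, which stripes never activate (all five
`R/L` case studies have a stripe-reduced discriminant of the supercritical
sign). Physical simulations break the symmetry through roundoff and
stochasticity; we emulate that explicitly and reproducibly with a small
`delta_y` cosine seed (`initial_density_2d(delta_y = )`; the case-study
tests use `delta_y = delta/2`). Near-threshold 2D runs are the slowest
objects in the package (the diffusion-stability step bound scales as
`dx^2 / D` with `D ≈ 0.7`); `max_steps` acts as a runtime guard and a
non-converged result can be resumed by passing its density back in.

## The particle experiments

`run_micro()` realizes the study conditions of the reference particle
runs: box `L = 3`, `R = 0.75`, `kappa = 2`, `nu_f = nu_d = 1`, initial
link fraction `xi_init = 0.1`, maximal displacement `delta_step = 0.1`,
default horizon `t_final = 20`, ensembles of 6 replicates, and initial
positions drawn from the cosine-perturbed density with `delta = 0.01` by
inverse-CDF sampling. Where a quantity was left open we fixed it once:
`n_bins = 60` histogram bins over `[-L, L]` (the literal estimator
`N_i / (2NL)` with bins of width `L/N_x` does not integrate to one; we
keep the bin geometry and normalize to unit midpoint mass), `dt_max = 0.1`
(`0.25` in the long mean-field sweeps, where the drift cap is the binding
constraint), and the `eps = 0` drift normalization `nu_f / (nu_d (N-1))` —
the unique choice that matches both the stationary per-pair linkage
probability of the finite-`eps` process and the mass-one macroscopic
equation; a raw pair sum would grow like `N` (`mean_field_norm = FALSE`
disables it for diagnostics).

Densities are estimated on the recentered configuration: all particles are
shifted by the circular mean `X_m = (L/pi) arg(Σ exp(i pi X_j / L))`, so
ensemble members whose aggregate drifted to different positions can be
averaged. Because near-threshold growth is slow (`1/lambda` time scale),
the experiment drivers also time-average the recentered density and the
order parameter `Q` over the final stretch of each run, which suppresses
the finite-`N` noise floor `E[Q^2] = 1/(N L^2)` far better than six
replicates alone.

**Transitional noise and metastability.** For the supercritical length
(`ell = 0.4725`) the particle ensembles cleanly bracket the macroscopic
threshold: every replicate aggregates at `D = 0.0038` and none at
`D = 0.0042` (horizons of `6e3`–`1.5e4` chosen as a few multiples of
`1/lambda`), locating the transition within 5% of `-Vhat_1`. For the
subcritical length (`ell = 0.3`) the transition is first-order: the
uniform state is metastable above threshold and finite-`N` fluctuations
nucleate the aggregated branch sporadically up to ~9% above `D_c` on long
horizons. Mirroring the reference practice of reading the main branch and
neglecting sporadic aggregation beyond it, the detection rule calls a
noise value aggregated only when *every* replicate ends on the aggregated
branch; with moderate horizons (`t_final = 2500`) this locates the
subcritical transition within 7%. These horizons, grids and the
`Q` thresholds (0.05/0.06, between the noise floor ~0.01 and the smallest
saturated branch ~0.1) are fixed in the tests with fixed seeds.

The headline consistency check overlays the recentered ensemble-mean
density (`N = 1000`, 6 replicates, `eps = 0`) on the macroscopic steady
profile at matched `(ell, D)`: max-norm discrepancy below 0.05 at
`ell = 0.4725, D = 0.003`, and matching multi-bump states deep in the
unstable regime.

## Problem sizes used by the test suite

The full study grids (14-point noise sweeps at 256 cells, five 2D cases at
128 cells to `xi* < 1e-7`, particle sweeps to `t = 1.5e4`) run in minutes
to hours; the shipped tests exercise the same code paths at sizes chosen
to keep the whole suite within a desk-scale budget: 128–256 cells in 1D,
32 cells per dimension and the `lambda >= 0.003` portion of the case-study
grid in 2D (supercritical case 1 vs subcritical case 5), `N = 1000`
particles, and the horizons listed above. All qualitative contrasts
(continuous vs jump transitions, stripe vs peaked profiles, micro–macro
agreement) are asserted at these sizes.

## What the simulations do and do not show

Everything here is synthetic: the particle simulator *is* the data
generator, and agreement between tiers validates the scaling limit and the
numerics, not any particular biological system. Known limitations:

* The solvers are first-order explicit; near-threshold 2D runs at fine
  grids are expensive, and implicit or higher-order time integration is
  out of scope.
* The weakly nonlinear amplitude prediction is an upper estimate with no
  error model; the degenerate collar below `alpha_c` is unclassifiable at
  this order.
* Subcritical transition locations measured from finite-`N` ensembles
  depend on horizon and ensemble size through nucleation; we fix a
  documented convention rather than model the nucleation kinetics.
* Finite-`eps` simulations carry an `O(eps^2)` step-size cost; the suite
  validates the link process against its Markov closed form and the
  `eps = 0` limit against the macroscopic tier, but full transition sweeps
  at several `eps` values are a compute-budget, not a code, limitation.
* 2D particle simulations are out of scope (cost), as are non-periodic
  domains, user-supplied potentials, link-length-dependent unlinking and
  particle birth/death.
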