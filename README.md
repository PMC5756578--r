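# netphase

Phase transitions in particle systems coupled by dynamical spring networks.

Many biological structures — adhering cell aggregates, cross-linked fiber
networks, connective tissue — consist of agents that continually make and
break elastic connections with their neighbours. `netphase` implements a
complete model stack for such systems on periodic domains and the analysis
that predicts when the homogeneous state gives way to aggregates:

* **Agent-based simulator** (`run_micro()` and friends): `N` overdamped
  Brownian particles on `[-L, L)`; unlinked pairs within a detection radius
  `R` acquire spring links (rest length `ell`, stiffness `kappa`) at rate
  `nu_f/((N-1)eps^2)` per pair, links break at rate `nu_d/eps^2`, with the
  instantaneous-relinking limit `eps = 0` available as a mean-field pair
  interaction.
* **Macroscopic aggregation–diffusion equation**
  `∂t f = D Δf + ∇·(f ∇V∗f)` with the compactly supported spring potential
  `V(x) = [(|x|-ell)^2-(R-ell)^2] χ_{|x|≤R}`, solved by a
  positivity-preserving, well-balanced, free-energy-decreasing upwind
  finite-volume scheme in 1D (`run_to_steady_1d()`) and 2D
  (`run_to_steady_2d()`), with steady states detected through the residual
  `xi* = max |D log f + V∗f - mean|  < 1e-7`.
* **Linear and weakly nonlinear stability analysis**: Fourier modes of `V`
  (closed form in 1D, Bessel–Struve in 2D via `struve_h()`), growth rates
  `lambda_k = -(pi^2 k^2/L^2)(D + Vhat_k)`, critical noise `D_c = -Vhat_1`,
  critical lengths, supercritical/subcritical classification
  (`bifurcation_type_1d()`, `vstar_discriminant()`,
  `supercritical_window_2d()`) and saturated-amplitude predictions
  (`amplitude_prediction()`).
* **Experiment drivers** regenerating the study tables and diagrams:
  `threshold_table_1d()`, `amplitude_table_1d()`, `threshold_table_2d()`,
  `sweep_bifurcation()`, `overlay_micro_macro()`, plus a thin command-line
  front end at `inst/scripts/netphase-cli.R`.

## Worked example

```r
library(netphase)

p <- net_params(D = 0.0030, ell = 0.4725)   # R = 0.75, L = 3 defaults

# where is this parameter point in the phase diagram?
critical_lengths_1d(p)
#> $ell_c      0.494743  (uniform state stable for all D beyond this length)
#> $ell_star   0.4530284 (bifurcation changes type here)
#> $D_star     0.00742777
bifurcation_type_1d(p)$regime
#> [1] "supercritical"
growth_rate(1, params = p)$growth_rate     # distance above threshold
#> [1] 0.001053535

# what amplitude should the aggregate saturate at?
amplitude_prediction(0.001, p)[c("A_sat", "rho_th")]
#> $A_sat   0.1094073
#> $rho_th  0.3428013

# run the macroscopic equation to its steady state
res <- run_to_steady_1d(params = p, n_cells = 256)
res
#> <steady_state_result> T_max = 7824 (converged), Q = 0.2217, |rho|_num = 0.3304
```

The measured perturbation amplitude `|rho|_num = 0.3304` sits within a
percent of the grid-converged value and within the expected tolerance of
the analytic upper estimate `0.3428`; the order parameter `Q` (first-mode
amplitude of the steady density) is positive because `D < D_c = 0.00396`,
and decays continuously to zero as `D` approaches the threshold — the
supercritical signature. The particle tier reproduces the same profile:

```r
ov <- overlay_micro_macro(0.4725, 0.003,
                          config = micro_config(N = 1000, n_replicates = 6,
                                                t_final = 4000, seed = 5,
                                                dt_max = 0.25, n_bins = 48))
ov$l_inf
#> [1] 0.03953451   # max-norm gap between particle ensemble and PDE profile
```

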