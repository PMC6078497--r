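# gridperturb

Simulation and analysis toolkit for discriminating the circuit mechanism
behind grid-cell firing with **global perturbations** and the
**distribution of relative phase shifts (DRPS)**.

## The problem

Grid cells fire in spatially periodic patterns. Several mechanistically
distinct circuit models reproduce that firing equally well: recurrent
continuous-attractor networks that are *aperiodic* (local connectivity,
free boundaries), *partially periodic* (local connectivity on a torus) or
*fully periodic* (global connectivity on a torus), and *feedforward*
models in which grid tuning is inherited from upstream inputs. Activity
recordings alone cannot tell them apart. This package implements a
perturbation-based protocol that can: globally perturb the gain of
recurrent inhibition (γ_inh), the synaptic time constant (τ_syn), or —
through a conductance-based variant — temperature, and read out the
signature each architecture leaves in cell–cell relationships.

The central analysis object is the DRPS. Each cell has a phase within the
periodic population pattern; a perturbation that stretches the pattern by
a factor `1 + α` shifts the phase of a cell K periods from the expansion
focus by K *quanta*, where the quantum is

    Δ = α / (1 + α).

The histogram of pre-to-post changes in pairwise relative phase (the
DRPS, built from spatial tuning curves and therefore observable from a
handful of simultaneously recorded cells) is then multi-peaked with
`2M` peaks for an M-bump pattern (resolvable while `MΔ < 1/2`), and its
width σ_DRPS grows differently with perturbation strength in each
architecture: smoothly (aperiodic), in a step to maximal width (partially
periodic), or not at all (fully periodic and feedforward — separated from
each other by whether the spatial tuning period responds).

## What's inside

- `network_config()`, `build_weights()`, `apply_perturbation()` — the
  1D two-excitatory-population + inhibitory-population attractor
  networks (400 + 400 E, 160 I) in all three recurrent topologies.
- `run_lnp()` — linear-nonlinear spiking dynamics with sub-Poisson
  (gamma-renewal, ISI CV = 0.5) spike generation, velocity-modulated
  input, Rcpp/Armadillo core.
- `run_chh()`, `q10_scale()` — regular-spiking cortical Hodgkin–Huxley
  variant with Q10 temperature scaling (amplitudes ×1.3 / 10 °C, time
  constants ×3 / 10 °C) to predict the effect of cooling.
- `tuning_curve()`, `tuning_period()`, `population_spectrum_stats()`,
  `velocity_response()` — occupancy-normalized spatial tuning and
  population-pattern measures.
- `drps()`, `count_peaks()`, `infer_alpha()`, `periodicity_score()`,
  `bootstrap_phase_uncertainty()`, `subsample_drps_distance()` — the
  DRPS in both constructions, stretch-factor inference by comb
  correlation, and robustness analyses.
- `run_protocol()`, `classify_architecture()` — the end-to-end decision
  tree: simulate baseline + increasing perturbation strengths, measure,
  classify.
- `grid_place_model()`, `familiar_novel_separation()` — the grid→place
  Hebbian association model showing that learned place responses are not
  spuriously triggered in novel environments.

## Worked example

```r
library(gridperturb)

# idealized five-bump pattern, 10% expansion
pat <- idealized_pattern(N = 100, lambda_pop = 20, alpha = 0.10)
d   <- drps(pat$pre, pat$post, mode = "per_cell_population")
count_peaks(d)$n_peaks      # 10  (= 2M quantal peaks)
count_peaks(d)$spacing      # 0.095 (~ Delta = 0.1/1.1 = 0.0909)
infer_alpha(pat$pre, pat$post)$alpha_hat   # 0.1

# simulate the aperiodic network and perturb inhibition
cfg <- network_config("aperiodic", seed = 1)
w   <- build_weights(cfg)
rep <- run_protocol("aperiodic", "gamma_inh",
                    strengths = c(1.05, 1.15, 1.33, 1.66),
                    duration_s = 60, n_cells = 20, seed = 1)
rep$series[, c("strength", "period_change", "drps_width")]
#  strength period_change drps_width
#      1.05        0.0024      0.056
#      1.15        0.1711      0.131
#      1.33        0.2965      0.200
#      1.66        0.6686      0.202
rep$classification$label    # "aperiodic": sigma_DRPS grows smoothly
```

The σ_DRPS column is the decision variable: in the same protocol a fully
periodic network stays below ~0.03 at every strength while its tuning
period still changes, and a partially periodic network jumps to maximal
width in a single step.

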