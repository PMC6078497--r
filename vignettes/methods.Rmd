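---
title: "Models, measures and design choices in gridperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, measures and design choices in gridperturb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the measures it
computes, and the choices made where the design was genuinely open. It is
the companion to the function reference; nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The network models

Three recurrent architectures share one cell layout: two excitatory
populations receiving leftward/rightward velocity input (`EL`, `ER`, 400
cells each) and one inhibitory population (`I`, 160 cells — the cortical
1:5 ratio). Connectivity blocks are shifted Gaussians in the offset
coordinate `x_ij = i - γ j` (γ the size ratio, kept real-valued):
E→I Gaussians (η = 11.5, Δ = ∓2, σ = 4), I→E Gaussians with a central cut
and a direction-selective Heaviside window (η = 4, Δ = ±8, σ = 10,
μ = ∓1, δ = 3), and an I→I sum of two shifted Gaussians with the centre
removed (η = 12, Δ = 4, σ = 6, δ = 3). A variant adds E–E blocks with its
own table. The Heaviside convention is Θ(0) = 1.

* **Partially periodic**: offsets wrapped on the target ring
  (`wrap_norm`), periodicity scale ρ = 1.
* **Fully periodic**: same, with every shift and width stretched by
  ρ = 11, making connectivity effectively global; the pattern period is
  then fixed by the connectivity.
* **Aperiodic**: wrapped norms replaced by absolute values, and both
  weights and inputs multiplied by a smooth envelope
  `A_i = exp[-a0 ((r_i - κN)/((1-κ)N))^2]` beyond a flat central fraction
  κ (κ = 0.3, a0 = 30), which tapers activity toward the free boundaries.

Blocks store connection *magnitudes*. The inhibitory sign is applied
where the physics needs it: negatively in the rate-model input sum, and
through the −80 mV reversal potential in the conductance model. The
global perturbations are `γ_inh` (multiplies every inhibitory-source
block) and `τ_scale` (multiplies the synaptic time constant).

## 2. LNP dynamics

Rates are threshold-linear in the summed input; the default
(multiplicative) input is `G = [α_vel (G_rec + G0) + G0'] A` with
G0 = 50, G0' = 0 (I) / 15 (E), and `α_vel = 1 + β_vel v·ê_P`
(β_vel = 1; ê = ±1 for ER/EL, 0 for I). An additive mode with
W_vel = 200 is available. Spikes are drawn by time-rescaled gamma
renewal of order 4: the integrated rate is compared against successive
Gamma(4, mean 1) thresholds, giving ISI CV = 0.5 at constant rate while
preserving the mean rate exactly. Synapses integrate spikes with
`ds/dt = -s/τ_syn + Σ δ(t - t_spike)` (τ_syn = 30 ms), Euler step
dt = 0.5 ms (a warning fires if dt/τ_syn > 0.1). The Euler loop runs in
C++ (RcppArmadillo); weight matrices are stored sparse after dropping
entries below 1e-10 of the block maximum, which is exact to within
floating noise for the Gaussian profiles. All randomness flows through
R's RNG, so a seed makes runs bit-reproducible.

Pattern formation is an emergent outcome, not an input: the default
aperiodic network settles into a multi-bump pattern with a population
period near 15–16 neurons (I population) and pattern-quality (gridness)
well above the white-noise floor, and the pattern translates with
velocity input, producing spatially periodic single-cell tuning with a
period near 80–100 cm.

## 3. CHH dynamics

The conductance-based variant uses regular-spiking cortical neurons
(leak, fast K, slow M-type K, Na) with conductances
(g_L = 0.1, g_K = 5, g_M = 0.07, g_Na = 50 mS/cm², C_m = 1 µF/cm²,
V_L = −70, V_K = −90, V_Na = 50 mV), synaptic reversals 0/−80 mV, bias
I0 = 3 µA/cm², dt = 0.025 ms, τ_syn = 15 ms, β_vel = 0.8. Spikes are
upward 0 mV crossings. Two sign conventions had to be fixed by the
physics rather than the notation: the bias I0 is depolarizing (it seeds
activity, like the positive LNP bias), and inhibition acts through its
reversal potential.

The gate rate functions come from the published regular-spiking
cortical neuron literature; the package carries one standard set
(Traub-type kinetics with threshold shift VT = −56.2 mV; slow gate with
τ_max = 1000 ms) in `chh_params()`, swappable in one place. One
consequence of that freedom: translating the rate-model weight tables by
the conductance factor 0.0015 leaves the conductance network slightly below
its pattern-forming threshold, because conductance inputs are weighted by
driving force and the inhibitory driving force near rest (~20 mV) is
several-fold smaller than the excitatory one (~60 mV). `run_chh()`
therefore applies an explicit `inh_scale` (default 2) to inhibitory
conductances, restoring the rate model's effective E/I balance; the
factor is a visible argument, not folded into the weight tables.

Temperature enters through Q10 factors relative to T0 = 36 °C:
amplitudes (conductances and synaptic weights) scale by `1.3^((T-T0)/10)`
and all time constants by `3^(-(T-T0)/10)`. `q10_scale()` applies the
scaling to all parameters or to the ionic or synaptic group alone, and it
composes: scaling 36→31→26 equals 36→26 exactly. In simulation the two
groups pull the population period in opposite directions under cooling
(ionic-only contracts, synaptic-only expands); at 30 °C they nearly
cancel in this implementation, while at 26 °C the synaptic slowing wins
and the net period change is reliably an expansion. The tests assert the
opposing directions at 30 °C and the net expansion at 26 °C.

## 4. Trajectories

Only two properties of the trajectory are normative: reproducibility
from a seed, and near-uniform coverage (max/min occupancy over 1 cm bins
below 3 for 60 s runs). A plain random-walk velocity process cannot meet
the coverage bound on these time scales — it dithers and parks; the
generator therefore emulates track-running locomotion: direction
persists until a wall is reached, speed is an Ornstein–Uhlenbeck-smoothed
positive process (mean 0.25 m/s, SD 0.1, clipped to [0.05, 0.5] m/s),
and velocity is flipped *before* any step that would leave the track so
that position increments equal `v·dt` exactly. The default track is
200 cm; protocol measurement runs use 400 cm so that several grid
periods fit on the track (the emergent spatial period is ~80–100 cm).
What this generator does not emulate: 2D foraging, running-speed
rhythmicity, or behavioral state changes — tests passing on it say
nothing about those.

## 5. Measures

**Tuning curves**: spike counts in 1 cm bins normalized by occupancy
time, smoothed with a 5-bin boxcar (edge windows truncated and
renormalized); unvisited bins are filled by linear interpolation and
flagged. **Tuning period**: wavelength of the largest nonzero-frequency
power-spectrum peak, with parabolic (log-power) interpolation of the
peak — without it, periods are quantized to integer divisors of the
track length and genuine few-percent changes are invisible.
**Amplitude**: mean rate density. **Population period and gridness**:
per activity frame, the middle half of the population vector is
normalized (mean-subtracted, divided by the SD), its power spectrum
rescaled by 2/L²; gridness is the largest nonzero-frequency power (1 for
a pure sinusoid), the period is its wavelength, both averaged over the
last 10000 frames. Two refinements to the period readout: parabolic peak
interpolation (as above), and a subharmonic correction — when a
subharmonic bin of the largest peak carries at least half its power, the
subharmonic is taken as the pattern frequency. The correction matters at
strong inhibitory gain, where bumps become narrow and the second
harmonic of the bump spacing can carry the most power; without it the
period-versus-gain trend shows a spurious collapse at γ_inh = 1.66.
**Velocity response**: pattern displacement relative to a reference
frame, tracked by circular cross-correlation with sub-bin interpolation,
unwrapped modulo the population period, smoothed with a 4 s moving
average; the speed is averaged over the middle half of a 10 s
measurement. **Inclusion rule**: all cells in ring topologies, the
central 3/4 in aperiodic networks.

**Relative phase**: the offset of the central cross-correlation peak of
two tuning curves, as a fraction of the shared period, in [−1/2, 1/2).
The default estimator reads the offset from the phase of the
cross-spectrum at the shared pattern frequency — mathematically the
location of the cross-correlation's fundamental component — because the
literal discrete peak scan occasionally locks onto a secondary peak on
minute-scale noisy curves, producing half-cycle outliers that triple the
σ_DRPS noise floor; the discrete scan remains available
(`method = "xcorr_peak"`) and the two agree on clean curves. The 2D
version cross-correlates rate maps, obliquely projects the central-peak
displacement onto the lattice axes and wraps each component into
[−1/2, 1/2).

## 6. The DRPS and its statistics

Shifts are differences of relative-phase magnitudes (Lee distance),
`|δ_pre| − |δ_post|`, histogrammed into 200 bins over [−1/2, 1/2] and
smoothed with a circular 2-bin Gaussian; σ_DRPS is the sample SD of the
shifts. Peaks are local maxima of the smoothed histogram away from zero
shift with prominence ≥ 5% of the maximal bin. Two resolution limits are
worth knowing. First, the 2-bin Gaussian cannot resolve quanta closer
than about five bins (Δ ≲ 0.025): at α = 0.02 the quantal structure is
perfectly visible in the raw histogram (`count_peaks(smoothed = FALSE)`)
but absent from the smoothed one. Second, in the pairwise construction
the outermost quanta are carried by very few pairs; the clean `2M` peak
count is a property of the per-cell population-phase construction, which
is also how the idealized-pattern analyses are built.

The known-α transform maps matched phase pairs to exactly M clusters
spaced α apart at the true stretch factor. `infer_alpha()` scans a
candidate grid (step 0.005), correlating each transformed histogram with
an indicator comb. Two details make the inference robust: the comb's
teeth start at α (a zero-shift cluster exists for any candidate and
carries no spacing information, so bins below α/2 are masked), and each
tooth is padded one bin to either side so cluster mass falling on a bin
boundary still registers. Recovery is exact to the grid step for
α ∈ {0.05, 0.1}, M ∈ {3, 5}, down to 20-cell subsamples.

The periodicity score smooths (circularly), normalizes, and rescales the
power spectrum by 2/L²: 1 for a pure sinusoid (exactly — circular
smoothing preserves sinusoids up to rescaling, which the normalization
undoes), 0 for a flat histogram (zero-variance convention, with a
relative tolerance so FFT round-off does not masquerade as structure),
and below 0.2 on average for iid-uniform bins.

**Bootstrap phase uncertainty** resamples two cells' spike maps with
replacement (by default at the full spike count, so the uncertainty
scales with record length), re-estimates the relative phase per
resample, and returns the maximum-likelihood Rayleigh scale (= mode) of
the deviation magnitudes. On synthetic periodic Poisson maps the fitted
uncertainty follows T^(−1/2) (log–log slope −0.5).

## 7. The decision tree

`classify_architecture()` takes, per perturbation strength, the relative
changes in tuning amplitude and period and the DRPS width versus
baseline. Thresholds (all arguments): amplitude change ≥ 2% confirms the
perturbation is in effect; period change < 2% with a narrow DRPS means
feedforward; with a period change, σ_DRPS below `width_tol = 0.05` means
fully periodic — 0.05 sits just above the measured phase-noise floor of
60 s records (a fully periodic network with zero true shift reaches
σ_DRPS ≈ 0.03 from estimation noise alone); otherwise one step carrying
≥ 60% of the total width rise means partially periodic, and a steady
smooth rise means aperiodic. The protocol driver uses four strengths
{1.05, 1.15, 1.33, 1.66} for the two local architectures because σ_DRPS
saturates by γ = 1.33 — with only saturated points the smooth-versus-step
shapes are indistinguishable; the weakest strength provides the
sub-saturation sample that separates them.

## 8. Grid-to-place association model

Grid cells have sinusoidal tuning
`sin(2πx/λ_m + φ_i + φ̃_{m,k})` with fixed within-module phases and a
random module-wide phase per environment; grid→place weights are Hebbian
sums of grid activity at each place cell's preferred location over L = 2
familiar environments. Unstated parameters were fixed once at realistic
values: 4 modules, periods {30, 42, 59, 83} cm (ratio ≈ 1.4), 100 grid
cells/module, 200 place cells, 200 cm environments. The separation
statistic compares familiar-field activations with the *positional
distribution* of novel-environment activations: novel input is
zero-median, its 95th percentile sits below the median familiar field
activation, and fewer than 10% of novel positions exceed that level. A
stricter statement — per-cell novel *maxima* below familiar field peaks —
does not hold for sinusoidal tuning at any module count we examined:
with incommensurate periods there is almost always some position where
several modules align by chance. Realistic (sparser, sharper) tuning
would only increase the separation.

## 9. Problem sizes and numerical notes

The test suite exercises the full 400+400+160-cell networks. Population
periods are measured from 12–15 s zero-velocity runs (last 10000 frames
at dt = 0.5 ms); protocol conditions use 60 s quasi-random trajectories
with 20 sampled cells (190 pairs); CHH runs are 3–4 s at dt = 0.025 ms
with frames from 10 ms spike-count bins smoothed over 50 ms; the
bootstrap scaling uses 2–32 min synthetic records at dt = 5 ms with 100
resamples. Degenerate inputs are defined, not crashed on: flat curves
give NA periods, zero-variance frames are skipped, empty DRPS inputs and
non-positive perturbation factors are errors.

Known limitations: 1D networks only (2D claims are exercised through
idealized phase sheets); the CHH operating point depends on an
externally-sourced kinetics set and an explicit E/I rebalancing factor;
classifier thresholds are calibrated to minute-scale records and should
be revisited for much longer or shorter recordings.
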