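---
title: "Methods: phase-locking statistics and mechanotransduction fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking statistics and mechanotransduction fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgnmech)
```

`sgnmech` analyzes patch-clamp recordings from mechanically sensitive
auditory neurons: spike-train phase locking under sinusoidal stimulation,
and the biophysical curve fits that characterize the mechanically
activated (MA) conductance. This vignette is the package's account of the
underlying models, the choices made where a design was genuinely open, and
what its synthetic data can and cannot establish about real recordings.

## Units and conventions

Internally everything is in ms, mV, pA, nS, um, uM, and radians. Injected
current is specified in nA at the user surface (stimulus descriptors) and
converted to pA at the integrator, because stimulus protocols are quoted
in nA while measured currents are quoted in pA. Phases live on
`[0, 2*pi)`; the phase of a spike at time `t` relative to a sinusoid of
frequency `f` Hz and onset `t0` is `2*pi*f*(t - t0)/1000 mod 2*pi`. The
polar angle of a combined-stimulation condition is the phase lead of the
current relative to the mechanical stimulus. The command-line surface
reports degrees.

## Circular statistics

For spike phases `phi_i`, the vector strength is the mean resultant
length `VS = |sum(exp(1i * phi_i))| / n` — equivalently, the modulus of
the cycle histogram's fundamental Fourier component divided by the mean
rate. Both routes are implemented (`vector_strength()`,
`histogram_vs()`) and the test suite asserts they agree to better than
1e-3 at 360 bins; the spike-wise form is the primary one because it has
no binning error.

Significance uses the Rayleigh statistic `Z = n * VS^2`. The naive
`p = exp(-Z)` is anticonservative at realistic spike counts, so
`rayleigh_p()` applies the standard second-order corrected series

```
p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]
```

clipped to `(0, 1]`. Under uniform phases at `n = 50` the empirical
type-I error of the `p < 0.05` criterion is within `[0.04, 0.06]` over
10^4 replicates (checked in the test suite). A vector-strength estimate
is flagged invalid below `min_spikes_for_vs` (default 5; summary tables
in this literature report NA at low rates without stating a cutoff, so a
small explicit one was chosen).

Cycle histograms default to 36 bins (10 degrees); published figures in
this area do not state a bin width, and 36 balances resolution against
per-bin counts at the few-hundred-spike scale. Bins are half-open
`[edge_k, edge_{k+1})`.

### Peak-splitting detection

Peak-splitting — two preferred firing phases per stimulus cycle — is
described visually in the experimental literature; no published algorithm
exists, so `count_peaks()` defines one: smooth the cycle histogram with a
wrapped Gaussian kernel (SD 15 degrees), then count circular local maxima
at or above 25% of the tallest peak and separated by at least 60 degrees.
A flatness guard (smoothed max/mean below 1.5) marks structureless
histograms unreliable rather than reporting a mode count as meaningful.
The defaults were chosen so that single von Mises components with
concentration `kappa = 4` and balanced two-component mixtures half a
cycle apart (about 500 spikes) are classified correctly in at least 95%
of seeded runs — the regime of the peak-splitting observations the
detector is meant to flag.

### Polar summaries

`polar_summary()` condenses an 8-angle sweep (0 to 315 degrees in 45
degree steps): per-angle rate is averaged over repetitions and normalized
to its maximum; per-angle VS pools spike phases across repetitions
(pooling, rather than averaging per-repetition VS, keeps the estimate
well-defined at low counts and matches how repeated sweeps are averaged
in practice). Each magnitude set is condensed to a resultant
`R = sum(m_k * exp(1i * theta_k))` with normalized magnitude
`|R| / sum(m_k)`. Because no weighted-resultant significance procedure is
standard, a seeded permutation test (default 10^4 shuffles of the
magnitudes across angles) supplies the p-values; VS entries that are
invalid (too few spikes) are dropped from both numerator and denominator.

## Curve fits

All nonlinear fits use Levenberg–Marquardt with box constraints
(`minpack.lm`), a data-driven start plus seed-jittered multistart
replicates, and a cost tolerance of 1e-10, so results are deterministic
given data and seed.

- **Boltzmann activation.** `p_o(X) = 1/(1 + exp(-s (X - X_0.5)))` with
  `s > 0`, so open probability *increases* with displacement; the slope
  maps to a gating force `z = s * kB * T * 1e6` N at the configured
  temperature (default 295 K, room temperature). The two-component
  variant is a weighted sum of two single-Boltzmann terms — the
  conventional well-formed generalization; weight-1 reduces to the
  one-component model (tested).
- **Dose-response.** The standard Hill block
  `I(C) = (I_i - I_f)/(1 + (C/IC50)^p) + I_f`, consistent with IC50
  semantics. Where a Hill coefficient is needed but unknown, 1 is used.
- **Bi-exponential decay.** Multistart over log-spaced time-constant
  pairs; components are ordered `tau1 < tau2`. If the fitted constants
  collapse (`tau2/tau1 < 1.5`) the model is refit as a single
  exponential, with a warning and a flag in the result — reporting two
  indistinguishable constants would be noise.
- **I-V regression.** Ordinary least squares; conductance is the slope in
  nS (pA/mV) and the reversal potential the zero-current crossing. A
  zero slope leaves the reversal potential undefined and flagged.

Open probability from a displacement-clamp current series is computed as
`p_o = I(X) / max|I|` (`po_from_peaks()`); the normalization is stated
here because published summaries report `P_o` without defining it.

## The synthetic-data generator

`gen_phase_locked_train()` draws at most one spike per stimulus cycle
(probability `rate/frequency`, capped at 1 — matching firing rates at or
below the stimulus frequency seen in this preparation) with phase from a
von Mises mixture. The mean resultant length of a von Mises distribution
is `I1(kappa)/I0(kappa)`, which the generated trains recover within
sampling error (property-tested at `kappa` in 0.5–4 with 10^4 spikes).
`gen_curve_data()` adds i.i.d. Gaussian noise to the model curves on
protocol-shaped default grids (displacement steps 0–1.2 um in ~0.24 um
increments; holding voltages −90 to 90 mV in 30 mV steps).

### The neuron simulator

`simulate_neuron()` is a leaky integrate-and-fire membrane with an MA
conductance:

```
C_m dV/dt = -g_l (V - e_l) + I_inj(t) + I_MA(t) + noise
I_MA = (1 - block_fraction) * g_ma * D(t) * (e_ma - V)
```

`D(t)` couples instantaneous Boltzmann activation `p_o(X(t))` to
adaptation through two first-order states `z_i` relaxing toward `p_o`
with time constants `tau1`, `tau2`:
`D = a_ss * p_o + a1 * (p_o - z1) + a2 * (p_o - z2)`, clipped at zero.
This is the simplest kinetic scheme whose step response is exactly the
bi-exponential decay the fitting suite assumes (verified in a
voltage-clamp-analog test); only the decay *form* is empirically
constrained, not the scheme. Clipping at zero prevents a transiently
negative (unphysical) conductance after a displacement is released.

Two further choices:

- The resting open probability `p_o(0)` is absorbed into the leak — the
  drive uses `p_o(X) - p_o(0)` — so an unstimulated membrane sits exactly
  at `e_l`. Without this the standing MA current would redefine the
  resting potential and every threshold calibration with it.
- Sinusoidal *displacement* is half-wave rectified (the probe pushes; it
  cannot pull the membrane), so a displacement stimulus of amplitude `A`
  excursions over `[0, A]`.

Integration is fixed-step explicit Euler (default `dt = 0.02` ms, with a
precondition `dt <= 0.1 * tau1`) with a divergence guard that names the
offending step. Spikes are threshold crossings with reset and an absolute
refractory period; a stereotyped 1 ms triangular excursion to +20 mV is
painted into the returned voltage trace at each spike so the detection
stage (0 mV amplitude criterion) can be exercised end to end. Per-step
Gaussian current noise of SD `noise_sd` pA is applied at the integration
step; its effect therefore scales with `dt`, which is held fixed within
any comparison.

### Parameters: measured vs calibrated

The MA pathway defaults are measured values for apical spiral ganglion
neurons: `g_ma` 3.2 nS, `e_ma` −1.4 mV, `x_half` 0.42 um, `tau1` 3.6 ms,
`tau2` 24 ms. The membrane shell is *not* experimentally constrained —
published recordings from this preparation do not report capacitance,
leak, or threshold for a point-neuron reduction — so those defaults
(`c_m` 10 pF, `g_l` 1 nS giving a 10 ms membrane time constant, `e_l`
−62 mV at the reported resting potential, `v_th` −38 mV, `v_reset`
−70 mV, refractory 1 ms, Boltzmann slope 8 /um) are calibration choices,
fixed once so that the defaults reproduce the combined-stimulation
phenomenology: a 0.05 nA sinusoidal current alone and a 0.35 um
sinusoidal displacement alone are each subthreshold at 50 Hz, while their
in-phase combination fires; the antiphase combination is suppressed
relative to in-phase. The adaptation split `a1/a2/a_ss = 0.5/0.3/0.2`
reflects a predominantly fast-decaying MA current with a steady-state
component.

For the eight-angle sweep (`simulate_polar_sweep`) the default
displacement amplitude is larger (0.45 um) with per-step noise of 60 pA:
in that regime the current trough can veto mechanically driven firing and
noise exposes both competing depolarization phases, so the sweep shows
the experimentally observed alignment — the angle bin minimizing the
normalized rate also minimizes VS, with peak-splitting between. The
alignment is stable across master seeds (tested at ±45 degrees).

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical assertions are stable: 10^4-spike
trains for vector-strength recovery, 10^4 replicates for Rayleigh
calibration, 100 seeded replicates per fit family for noisy parameter
recovery (dose-response uses 9 concentrations spanning 0.05–30 uM with 4
cells per concentration; decay fits use 10 kHz sampling over 150 ms), 100
seeded runs for the peak-splitting classifier, and 2 s sweeps at
`dt = 0.05` ms with 3 repetitions per angle for the simulator
phenomenology.

## Limitations

The generator emulates the *statistical structure* the analysis assumes —
von Mises phase concentration, Gaussian curve noise, Poisson-thinned
cycle occupancy — not the biology that produces it. Real recordings add
bursting, adaptation of the spike generator itself, electrode drift,
stimulus artifacts, and cell-to-cell parameter spread; passing tests on
synthetic data validate the estimators and fits, not the biological
interpretation of any particular recording. The simulator is
phenomenological: it has no conductance-based spike machinery, no
synaptic input, and no cochlear micromechanics, and its membrane shell is
a calibration, so simulated spike counts and latencies support
qualitative direction checks (slower ramps, longer latency; antiphase,
suppression), never quantitative predictions. Rayleigh p-values assume
independent spike phases; strong serial dependence (e.g. bursting) will
inflate significance.
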