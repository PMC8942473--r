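# sgnmech

Spiral ganglion neurons (SGNs), the primary auditory neurons, turn out to
be mechanically sensitive themselves: minute displacement of their soma or
unmyelinated dendrite activates a non-selective cation conductance that
interacts with injected current to shape firing rate and spike timing.
`sgnmech` is an R toolkit for analyzing exactly this kind of patch-clamp
experiment. It is aimed at electrophysiologists who record voltage or
current traces under sinusoidal, step, or ramp stimulation and need a
reproducible pipeline from raw traces to phase-locking statistics and
biophysical curve fits — plus a synthetic-data generator and a
phenomenological neuron simulator that reproduce the statistical structure
the analysis assumes, so every stage can be validated end to end.

## What it computes

**Spike-train circular statistics.** For spikes at times `t_i` relative to
a sinusoid of frequency `f`, phases are `φ_i = 2πf·t_i mod 2π` and the
vector strength (synchronization index) is

    VS = |Σ exp(iφ_i)| / n

with `VS = 0` for a flat cycle histogram and `VS = 1` for perfect phase
locking. Significance uses the Rayleigh statistic `Z = n·VS²` with the
finite-sample corrected p-value series; cycle histograms, a wrapped-Gaussian
peak counter for peak-splitting (two preferred firing phases per cycle),
and polar summaries over eight relative phase angles with normalized
resultant vectors `R = Σ m_k exp(iθ_k)` complete the set.

**Biophysical curve fits.**

- Boltzmann mechanotransduction activation
  `p_o(X) = 1 / (1 + exp(−s(X − X₀.₅)))` (one or two components), with
  gating force `z = s·kT`;
- Hill dose–response block
  `I(C) = (I_i − I_f) / (1 + (C/IC₅₀)^p) + I_f`;
- bi-exponential current decay
  `y(t) = A₁·e^(−t/τ₁) + A₂·e^(−t/τ₂) + A_ss`;
- linear I–V regression `I = g·(V − E_rev)`.

**Simulation.** A leaky integrate-and-fire membrane carrying a mechanically
activated conductance `I_MA = g_MA·D(t)·(E_MA − V)`, where `D(t)` combines
Boltzmann activation of displacement with bi-exponential adaptation. Its
calibrated defaults reproduce the hallmark phenomenology of combined
stimulation: subthreshold current and subthreshold displacement that become
suprathreshold in phase, and rate suppression with peak-splitting at
unfavorable phase angles.

## Worked example

```r
library(sgnmech)

## a phase-locked train (von Mises concentration kappa = 4) and its stats
train  <- gen_phase_locked_train(rate = 40, frequency = 100,
                                 duration = 2000, kappa = 4, seed = 42)
phases <- spike_phases(train)
vector_strength(phases)
#> <phase_lock_stats> VS = 0.8891, mean phase = 356.4 deg, n = 74, Rayleigh p = 1.851e-24

## noisy displacement-clamp series, fitted
act <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                      noise_sd = 0.02, seed = 7)
act$y <- pmin(pmax(act$y, 0), 1)
fit_boltzmann(act)
#> <boltzmann_fit> 1 component(s): X_0.5 = 0.4291 um, slope = 7.707 /um, z = 3.14e-14 N (RSS 0.00305, n = 6)

## combined subthreshold stimulation: 0 + 0 -> 26 spikes
p    <- neuron_params()
cur  <- sinusoid_stimulus("current", 50, 0.05, duration = 1000)      # nA
mech <- sinusoid_stimulus("displacement", 50, 0.35, duration = 1000) # um
length(simulate_neuron(p, cur,  NULL, duration = 1000, dt = 0.05)$spikes$times)  # 0
length(simulate_neuron(p, NULL, mech, duration = 1000, dt = 0.05)$spikes$times)  # 0
length(simulate_neuron(p, cur,  mech, duration = 1000, dt = 0.05)$spikes$times)  # 26
```

The vector strength 0.889 sits within sampling error of the theoretical
von Mises value `I₁(4)/I₀(4) ≈ 0.864`; the fitted midpoint 0.429 um
recovers the generating 0.42 um from noisy data; and the spike counts show
the combined-stimulation threshold interaction. An eight-angle sweep
(`simulate_polar_sweep`) then yields a polar summary in which the angles
of minimum normalized rate and minimum VS coincide — high firing rate is
accompanied by strong phase locking and vice versa:

```r
sw <- simulate_polar_sweep(neuron_params(noise_sd = 60), seed = 11,
                           config = analysis_config(rng_seed = 11,
                                                    permutations = 1000))
sw$summary
#> <polar_summary> 8-angle combined-stimulation sweep
#>   rate resultant: magnitude 0.266 at 349.6 deg (perm p = 0.00899)
#>   VS resultant:   magnitude 0.017 at 5.5 deg (perm p = 0.173)
```

A command-line wrapper with `generate`, `simulate`, `detect-spikes`,
`phaselock`, `polar`, `fit`, and `demo` subcommands is installed at
`inst/cli/sgnmech` (see `sgn_cli()`).

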