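#' Simulate an eight-angle combined-stimulation sweep
#'
#' Runs [simulate_neuron()] with a sinusoidal current and a sinusoidal
#' displacement whose relative phase is stepped through 0 to 315 degrees
#' in 45 degree increments (the polar angle is the phase lead of the
#' current relative to the mechanical stimulus), with several noisy
#' repetitions per angle, and condenses the result with
#' [polar_summary()]. Spike phases are referenced to a zero-phase
#' sinusoid at the stimulation frequency.
#'
#' @param params A [neuron_params()]; its `noise_sd` should be positive
#'   so that repetitions differ.
#' @param current_amp Current amplitude, nA.
#' @param mech_amp Displacement amplitude, um.
#' @param frequency Common stimulation frequency, Hz.
#' @param duration Stimulus duration per repetition, ms.
#' @param n_reps Repetitions per angle.
#' @param dt Integration step, ms.
#' @param seed Master seed; per-run noise seeds are derived from it.
#' @param config An [analysis_config()].
#' @return List with `summary` (a [polar_summary()]) and `conditions`
#'   (the per-angle lists of simulated spike trains).
#' @export
simulate_polar_sweep <- function(params, current_amp = 0.05,
                                 mech_amp = 0.45, frequency = 50,
                                 duration = 2000, n_reps = 3, dt = 0.05,
                                 seed = 1, config = analysis_config()) {
  angles_deg <- seq(0, 315, by = 45)
  ref <- sinusoid_stimulus("current", frequency, current_amp,
                           duration = duration)
  conditions <- lapply(angles_deg, function(a) {
    trains <- lapply(seq_len(n_reps), function(r) {
      p <- params
      p$noise_sd <- params$noise_sd
      p$seed <- stage_seed(seed, sprintf("sweep-angle%d-rep%d", a, r))
      cur <- sinusoid_stimulus("current", frequency, current_amp,
                               phase_offset = a * pi / 180,
                               duration = duration)
      mech <- sinusoid_stimulus("displacement", frequency, mech_amp,
                                duration = duration)
      sim <- simulate_neuron(p, current_stim = cur, mech_stim = mech,
                             duration = duration, dt = dt)
      sim$spikes
    })
    list(angle_deg = a, trains = trains)
  })
  summary <- polar_summary(conditions, stim = ref, config = config)
  list(summary = summary, conditions = conditions)
}

#' Derive a per-stage RNG seed from a master seed
#'
#' Deterministically fans a single master seed out to independent
#' substreams by hashing a stage label, so that pipeline stages are
#' reproducible yet decoupled.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer(h)
}
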