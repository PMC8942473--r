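# Canonical internal units: ms, mV, pA, nS, um, uM, radians.
# Injected current supplied in nA at the user surface is converted to pA
# (1 nA = 1000 pA) before it reaches the integrator.

.trace_kinds <- c(voltage = "mV", current = "pA", displacement = "um")

.normalize_units <- function(units) {
  u <- c("μm" = "um", "µm" = "um", "um" = "um",
         "mV" = "mV", "pA" = "pA")
  out <- unname(u[units])
  if (is.na(out)) stop("unknown units: ", units, call. = FALSE)
  out
}

#' Uniformly sampled recording trace
#'
#' Container for a voltage, current, or displacement series sampled at a
#' fixed interval, as produced by an episodic patch-clamp acquisition or by
#' [simulate_neuron()].
#'
#' @param samples Numeric vector of samples (non-empty, all finite unless
#'   `check = FALSE`).
#' @param dt Sampling interval in ms (> 0).
#' @param kind One of `"voltage"`, `"current"`, `"displacement"`.
#' @param units Units string; defaults to the canonical units for `kind`
#'   (mV, pA, um respectively) and must match them.
#' @param t0 Time of the first sample in ms.
#' @return An object of class `trace` with fields `t0`, `dt`, `samples`,
#'   `kind`, `units`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.1, kind = "voltage")
#' trace_times(tr)[1:3]
#' @export
trace <- function(samples, dt, kind = c("voltage", "current", "displacement"),
                  units = NULL, t0 = 0) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("no samples", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)", call. = FALSE)
  expected <- .trace_kinds[[kind]]
  if (is.null(units)) units <- expected
  units <- .normalize_units(units)
  if (!identical(units, expected))
    stop(sprintf("units '%s' inconsistent with kind '%s' (expected '%s')",
                 units, kind, expected), call. = FALSE)
  structure(list(t0 = as.numeric(t0), dt = dt, samples = samples,
                 kind = kind, units = units),
            class = "trace")
}

#' Sample times of a trace
#' @param x A [trace()].
#' @return Numeric vector of times in ms, same length as `x$samples`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + x$dt * (seq_along(x$samples) - 1L)
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s (%s), %d samples, dt = %g ms, t0 = %g ms\n",
              x$kind, x$units, length(x$samples), x$dt, x$t0))
  invisible(x)
}

#' Sinusoidal stimulus descriptor
#'
#' Describes a sinusoidal current injection or mechanical displacement.
#' The instantaneous waveform over the active window is
#' `amplitude * sin(2*pi*frequency*(t - onset) + phase_offset)`; a
#' displacement stimulus is half-wave rectified (the probe pushes but
#' cannot pull), so its excursion spans 0 to `amplitude`.
#'
#' @param modality `"current"` or `"displacement"`.
#' @param frequency Hz (> 0).
#' @param amplitude nA for current, um for displacement (>= 0).
#' @param phase_offset Radians.
#' @param onset Stimulus onset, ms.
#' @param duration Stimulus duration, ms (> 0).
#' @return Object of class `sinusoid_stimulus`.
#' @export
sinusoid_stimulus <- function(modality = c("current", "displacement"),
                              frequency, amplitude, phase_offset = 0,
                              onset = 0, duration) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(frequency), frequency > 0,
            is.numeric(amplitude), amplitude >= 0,
            is.numeric(duration), duration > 0)
  structure(list(modality = modality, frequency = as.numeric(frequency),
                 amplitude = as.numeric(amplitude),
                 phase_offset = as.numeric(phase_offset) %% (2 * pi),
                 onset = as.numeric(onset), duration = as.numeric(duration)),
            class = c("sinusoid_stimulus", "stimulus"))
}

#' Step or ramp stimulus descriptor
#'
#' A rectangular step (`slew_rate = 0`, instantaneous rise) or a linear
#' ramp to `amplitude` at the given slew rate, held until `onset + duration`.
#'
#' @param modality `"current"` or `"displacement"`.
#' @param amplitude nA for current, um for displacement (>= 0).
#' @param onset Onset, ms.
#' @param duration Duration, ms.
#' @param slew_rate Ramp speed in um/ms (or nA/ms); 0 means instantaneous.
#' @return Object of class `step_ramp_stimulus`.
#' @export
step_ramp_stimulus <- function(modality = c("current", "displacement"),
                               amplitude, onset = 0, duration,
                               slew_rate = 0) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(amplitude), amplitude >= 0,
            is.numeric(slew_rate), slew_rate >= 0,
            is.numeric(duration), duration > 0)
  structure(list(modality = modality, amplitude = as.numeric(amplitude),
                 onset = as.numeric(onset), duration = as.numeric(duration),
                 slew_rate = as.numeric(slew_rate)),
            class = c("step_ramp_stimulus", "stimulus"))
}

#' Evaluate a stimulus waveform on a time grid
#'
#' @param stim A stimulus descriptor, or `NULL` (returns zeros).
#' @param times Numeric vector of times in ms.
#' @return Numeric vector of stimulus values (nA or um) at `times`.
#' @export
stimulus_waveform <- function(stim, times) {
  if (is.null(stim)) return(numeric(length(times)))
  stopifnot(inherits(stim, "stimulus"))
  active <- times >= stim$onset & times < stim$onset + stim$duration
  out <- numeric(length(times))
  tt <- times[active] - stim$onset
  if (inherits(stim, "sinusoid_stimulus")) {
    w <- stim$amplitude * sin(2 * pi * stim$frequency * tt / 1000 +
                                stim$phase_offset)
    if (stim$modality == "displacement") w <- pmax(w, 0)
    out[active] <- w
  } else {
    if (stim$slew_rate <= 0) {
      out[active] <- stim$amplitude
    } else {
      out[active] <- pmin(stim$amplitude, stim$slew_rate * tt)
    }
  }
  out
}

#' Spike train bound to an optional stimulus descriptor
#'
#' @param times Strictly increasing spike times in ms, all within
#'   `[0, record_duration]`.
#' @param record_duration Record length in ms; defaults to the last spike
#'   time (or 0 for an empty train).
#' @param stimulus Optional [sinusoid_stimulus()] or [step_ramp_stimulus()].
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, record_duration = NULL, stimulus = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times contain NA", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (is.null(record_duration))
    record_duration <- if (length(times)) times[length(times)] else 0
  if (length(times) && (times[1L] < 0 || times[length(times)] > record_duration))
    stop("spike times must lie in [0, record_duration]", call. = FALSE)
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus"))
  structure(list(times = times, record_duration = as.numeric(record_duration),
                 stimulus = stimulus),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g ms%s\n", length(x$times),
              x$record_duration,
              if (is.null(x$stimulus)) "" else
                paste0(" (", class(x$stimulus)[1L], " attached)")))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundle of analysis-wide settings: the action-potential amplitude
#' criterion (membrane potential a valid spike must exceed, default 0 mV),
#' detector dead time, cycle-histogram bin count, minimum spike count for a
#' vector-strength estimate, recording temperature (used to convert the
#' Boltzmann slope to a gating force), RNG seed, and permutation count for
#' resultant-vector significance.
#'
#' @param spike_criterion mV; default 0.
#' @param dead_time ms; default 1.
#' @param n_bins Cycle-histogram bins (>= 8); default 36 (10 degree bins).
#' @param min_spikes_for_vs Minimum spikes for a valid VS (>= 2); default 5.
#' @param temperature Kelvin (> 0); default 295 (room temperature).
#' @param rng_seed Integer seed or `NULL`.
#' @param permutations Permutation count for polar-summary p-values.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(spike_criterion = 0, dead_time = 1, n_bins = 36,
                            min_spikes_for_vs = 5, temperature = 295,
                            rng_seed = NULL, permutations = 10000) {
  stopifnot(n_bins >= 8, min_spikes_for_vs >= 2, temperature > 0,
            dead_time >= 0, permutations >= 1)
  structure(list(spike_criterion = spike_criterion, dead_time = dead_time,
                 n_bins = as.integer(n_bins),
                 min_spikes_for_vs = as.integer(min_spikes_for_vs),
                 temperature = temperature,
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
                 permutations = as.integer(permutations)),
            class = "analysis_config")
}
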