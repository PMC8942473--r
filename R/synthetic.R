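# Synthetic-data generator: phase-locked spike trains (von Mises phase
# mixtures), noisy curve families for the fitting suite, and a
# phenomenological leaky integrate-and-fire neuron with a mechanically
# activated conductance.

# von Mises sampler (Best & Fisher 1979 wrapping rejection method).
# Uses the current RNG stream; callers seed via withr::with_seed.
.rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu %% (2 * pi), n))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    m <- max(n - i, 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- f[ok]
    s <- sign(u3[ok] - 0.5)
    take <- min(length(acc), n - i)
    if (take > 0L) {
      out[(i + 1L):(i + take)] <-
        (mu + s[seq_len(take)] * acos(pmin(pmax(acc[seq_len(take)], -1), 1))) %% (2 * pi)
      i <- i + take
    }
  }
  out
}

# Theoretical mean resultant length of a von Mises distribution.
.vm_resultant <- function(kappa) {
  if (!is.finite(kappa)) return(1)
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Generate a phase-locked spike train
#'
#' Emulates a neuron phase-locking to a sinusoidal stimulus. The record
#' is divided into `duration * frequency / 1000` whole cycles; each cycle
#' emits at most one spike with probability `rate / frequency` (capped at
#' 1, matching firing rates at or below the stimulus frequency), at a
#' phase drawn from a (mixture of) von Mises distribution(s). A
#' two-component mixture with means about half a cycle apart reproduces
#' peak-splitting: two preferred firing phases per stimulus cycle.
#'
#' @param rate Target mean firing rate, spikes/s (>= 0).
#' @param frequency Stimulus frequency, Hz.
#' @param duration Record duration, ms.
#' @param mean_phase Component mean phase(s), radians.
#' @param kappa Component concentration(s) (>= 0; `Inf` for a delta).
#' @param weights Component mixture weights (>= 0, summing to 1).
#' @param onset Stimulus onset, ms.
#' @param seed Integer seed; the output is bit-for-bit reproducible given
#'   the seed.
#' @return A [spike_train()] with a sinusoidal stimulus descriptor
#'   attached (current modality, zero phase offset).
#' @examples
#' tr <- gen_phase_locked_train(rate = 40, frequency = 50, duration = 2000,
#'                              kappa = 4, seed = 1)
#' vector_strength(spike_phases(tr))$vs
#' @export
gen_phase_locked_train <- function(rate, frequency, duration,
                                   mean_phase = 0, kappa = 4, weights = 1,
                                   onset = 0, seed = NULL) {
  stopifnot(rate >= 0, frequency > 0, duration > 0,
            length(mean_phase) == length(kappa),
            length(weights) == length(kappa))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  run <- function() {
    n_cycles <- floor(duration * frequency / 1000)
    p_spike <- min(rate / frequency, 1)
    fire <- stats::runif(n_cycles) < p_spike
    n <- sum(fire)
    comp <- if (length(weights) == 1L) rep(1L, n)
            else sample.int(length(weights), n, replace = TRUE, prob = weights)
    ph <- numeric(n)
    for (k in seq_along(weights)) {
      idx <- comp == k
      ph[idx] <- .rvonmises(sum(idx), mean_phase[k], kappa[k])
    }
    cyc <- which(fire) - 1L
    times <- onset + (cyc + ph / (2 * pi)) * 1000 / frequency
    spike_train(sort(times), record_duration = onset + duration,
                stimulus = sinusoid_stimulus("current", frequency, 0,
                                             onset = onset,
                                             duration = duration))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Generate noisy data from a model curve family
#'
#' Evaluates one of the package's model curves on a design grid and adds
#' i.i.d. Gaussian noise: `y = f(x; true_params) + N(0, noise_sd)`.
#' Families and their parameter names:
#' \describe{
#'   \item{boltzmann1}{`x_half`, `slope` (see [boltzmann_po()]); default
#'     grid 0 to 1.2 um in ~0.24 um steps (a displacement-clamp series).}
#'   \item{boltzmann2}{`x_half1`, `slope1`, `x_half2`, `slope2`, `w1`.}
#'   \item{dose}{`i_initial`, `i_final`, `c_half`, `hill_p` (see
#'     [hill_current()]); default grid is log-spaced 0.1 to 10 uM.}
#'   \item{biexp}{`a1`, `tau1`, `a2`, `tau2`, `a_ss` (see
#'     [biexp_current()]); default grid 0 to 100 ms.}
#'   \item{iv}{`conductance`, `e_rev` (see [iv_current()]); default grid
#'     -90 to 90 mV in 30 mV steps (a holding-voltage series).}
#' }
#'
#' @param family One of `"boltzmann1"`, `"boltzmann2"`, `"dose"`,
#'   `"biexp"`, `"iv"`.
#' @param true_params Named list of generating parameters for the family.
#' @param x Design grid; a family-specific default is used when `NULL`.
#' @param noise_sd Gaussian noise SD in the y units.
#' @param seed Integer seed for reproducibility.
#' @return `data.frame(x, y)`.
#' @export
gen_curve_data <- function(family = c("boltzmann1", "boltzmann2", "dose",
                                      "biexp", "iv"),
                           true_params, x = NULL, noise_sd = 0,
                           seed = NULL) {
  family <- match.arg(family)
  defaults <- list(
    boltzmann1 = seq(0, 1.2, by = 0.24),
    boltzmann2 = seq(0, 1.2, by = 0.12),
    dose = c(0.1, 0.3, 0.9, 1, 3, 10),
    biexp = seq(0, 100, by = 0.5),
    iv = seq(-90, 90, by = 30))
  if (is.null(x)) x <- defaults[[family]]
  p <- true_params
  y0 <- switch(family,
    boltzmann1 = boltzmann_po(x, p$x_half, p$slope),
    boltzmann2 = .boltzmann2_po(x, p$x_half1, p$slope1, p$x_half2,
                                p$slope2, p$w1),
    dose = hill_current(x, p$i_initial, p$i_final, p$c_half,
                        if (is.null(p$hill_p)) 1 else p$hill_p),
    biexp = biexp_current(x, p$a1, p$tau1, p$a2, p$tau2, p$a_ss),
    iv = iv_current(x, p$conductance, p$e_rev))
  add_noise <- function() y0 + stats::rnorm(length(x), 0, noise_sd)
  y <- if (noise_sd > 0) {
    if (!is.null(seed)) withr::with_seed(seed, add_noise()) else add_noise()
  } else y0
  data.frame(x = x, y = y)
}

#' Phenomenological neuron parameters
#'
#' Parameter bundle for [simulate_neuron()]: a leaky integrate-and-fire
#' membrane carrying a mechanically activated (MA) conductance with
#' Boltzmann activation and bi-exponential adaptation. The MA-pathway
#' defaults are the measured values for apical spiral ganglion neurons
#' (`g_ma` 3.2 nS, `e_ma` -1.4 mV, `x_half` 0.42 um, `tau1` 3.6 ms,
#' `tau2` 24 ms); the membrane shell (capacitance, leak, threshold) is a
#' calibration choice, not a measured quantity.
#'
#' @param c_m Membrane capacitance, pF.
#' @param g_l Leak conductance, nS.
#' @param e_l Leak (resting) potential, mV.
#' @param v_th Spike threshold, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @param refractory Absolute refractory period, ms.
#' @param g_ma Maximal MA conductance, nS (>= 0).
#' @param e_ma MA reversal potential, mV.
#' @param x_half Half-activation displacement, um.
#' @param slope Boltzmann slope s, 1/um.
#' @param a1,a2,a_ss Adaptation fractions (fast, slow, steady-state);
#'   must sum to 1.
#' @param tau1,tau2 Adaptation time constants, ms (`tau1 < tau2`).
#' @param noise_sd Per-step Gaussian current noise SD, pA.
#' @param block_fraction Fraction of the MA conductance blocked
#'   (pharmacological block), in `[0, 1]`.
#' @param seed Integer seed for the noise stream.
#' @return Object of class `neuron_params`.
#' @export
neuron_params <- function(c_m = 10, g_l = 1, e_l = -62, v_th = -38,
                          v_reset = -70, refractory = 1,
                          g_ma = 3.2, e_ma = -1.4, x_half = 0.42,
                          slope = 8, a1 = 0.5, a2 = 0.3, a_ss = 0.2,
                          tau1 = 3.6, tau2 = 24, noise_sd = 0,
                          block_fraction = 0, seed = NULL) {
  stopifnot(c_m > 0, g_l >= 0, g_ma >= 0, refractory >= 0,
            tau1 > 0, tau2 > 0, tau1 < tau2, noise_sd >= 0,
            block_fraction >= 0, block_fraction <= 1)
  if (abs(a1 + a2 + a_ss - 1) > 1e-8)
    stop("adaptation fractions a1 + a2 + a_ss must sum to 1", call. = FALSE)
  structure(list(c_m = c_m, g_l = g_l, e_l = e_l, v_th = v_th,
                 v_reset = v_reset, refractory = refractory, g_ma = g_ma,
                 e_ma = e_ma, x_half = x_half, slope = slope, a1 = a1,
                 a2 = a2, a_ss = a_ss, tau1 = tau1, tau2 = tau2,
                 noise_sd = noise_sd, block_fraction = block_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "neuron_params")
}

#' Simulate a mechanosensitive integrate-and-fire neuron
#'
#' Integrates a leaky integrate-and-fire membrane driven by an injected
#' current stimulus and a mechanically activated (MA) conductance:
#' `C_m dV/dt = -g_l (V - e_l) + I_inj + I_MA + noise`, with
#' `I_MA = (1 - block_fraction) * g_ma * D(t) * (e_ma - V)`. The MA drive
#' `D(t)` combines instantaneous Boltzmann activation `p_o(X(t))` with
#' bi-exponential adaptation: two first-order states `z_i` relax toward
#' `p_o` with time constants `tau1`, `tau2`, and
#' `D = a_ss * p_o + a1 * (p_o - z1) + a2 * (p_o - z2)` (clipped at 0),
#' so a displacement step produces an MA current decaying exactly as
#' `A1 exp(-t/tau1) + A2 exp(-t/tau2) + A_ss`.
#'
#' Threshold crossings trigger a spike: the time is recorded, the
#' membrane is reset and held for the refractory period, and a
#' stereotyped 1 ms triangular excursion to +20 mV is painted into the
#' returned voltage trace so that downstream spike detection (0 mV
#' amplitude criterion) sees a realistic target.
#'
#' @param params A [neuron_params()].
#' @param current_stim Injected-current stimulus (amplitude in nA), a
#'   [sinusoid_stimulus()] or [step_ramp_stimulus()] with modality
#'   `"current"`, or `NULL`.
#' @param mech_stim Displacement stimulus (amplitude in um), modality
#'   `"displacement"`, or `NULL`.
#' @param duration Simulation length, ms.
#' @param dt Integration step, ms; must satisfy `dt <= 0.1 * tau1`.
#' @return List with `voltage` (a [trace()]) and `spikes` (a
#'   [spike_train()] with the current stimulus attached when present,
#'   else the mechanical one).
#' @export
simulate_neuron <- function(params, current_stim = NULL, mech_stim = NULL,
                            duration, dt = 0.02) {
  stopifnot(inherits(params, "neuron_params"), duration > 0)
  if (dt > 0.1 * params$tau1 + 1e-12)
    stop("dt must be <= 0.1 * tau1 for a stable adaptation integration",
         call. = FALSE)
  if (!is.null(current_stim) && current_stim$modality != "current")
    stop("current_stim must have modality 'current'", call. = FALSE)
  if (!is.null(mech_stim) && mech_stim$modality != "displacement")
    stop("mech_stim must have modality 'displacement'", call. = FALSE)

  n <- as.integer(ceiling(duration / dt)) + 1L
  tt <- (seq_len(n) - 1L) * dt
  i_inj <- 1000 * stimulus_waveform(current_stim, tt)  # nA -> pA
  x_t <- stimulus_waveform(mech_stim, tt)              # um
  # The resting open probability at zero displacement is absorbed into the
  # leak, so the quiescent membrane sits exactly at e_l; the MA drive is
  # the activation above rest.
  po <- pmax(boltzmann_po(x_t, params$x_half, params$slope) -
               boltzmann_po(0, params$x_half, params$slope), 0)
  g_eff <- (1 - params$block_fraction) * params$g_ma

  noise <- if (params$noise_sd > 0) {
    gen <- function() stats::rnorm(n, 0, params$noise_sd)
    if (!is.null(params$seed)) withr::with_seed(params$seed, gen()) else gen()
  } else numeric(n)

  v <- numeric(n)
  v[1L] <- params$e_l
  z1 <- 0; z2 <- 0
  refr_until <- -Inf
  spike_times <- numeric(0)
  for (k in seq_len(n - 1L)) {
    p <- po[k]
    drive <- params$a_ss * p + params$a1 * (p - z1) + params$a2 * (p - z2)
    drive <- max(drive, 0)
    i_ma <- g_eff * drive * (params$e_ma - v[k])
    dv <- (-params$g_l * (v[k] - params$e_l) + i_inj[k] + i_ma +
             noise[k]) / params$c_m
    vk1 <- v[k] + dt * dv
    z1 <- z1 + dt * (p - z1) / params$tau1
    z2 <- z2 + dt * (p - z2) / params$tau2
    if (!is.finite(vk1))
      stop(sprintf("integration diverged at t = %.3f ms (step %d)",
                   tt[k + 1L], k), call. = FALSE)
    if (tt[k + 1L] < refr_until) {
      v[k + 1L] <- params$v_reset
    } else if (vk1 >= params$v_th) {
      spike_times <- c(spike_times, tt[k + 1L])
      refr_until <- tt[k + 1L] + params$refractory
      v[k + 1L] <- params$v_reset
    } else {
      v[k + 1L] <- vk1
    }
  }

  # paint stereotyped 1-ms triangular AP excursions peaking at +20 mV
  v_out <- v
  for (ts in spike_times) {
    k0 <- as.integer(round(ts / dt)) + 1L
    k_peak <- min(k0 + as.integer(round(0.5 / dt)), n)
    k_end <- min(k0 + as.integer(round(1 / dt)), n)
    if (k_peak > k0)
      v_out[k0:k_peak] <- seq(params$v_th, 20, length.out = k_peak - k0 + 1L)
    if (k_end > k_peak)
      v_out[k_peak:k_end] <- seq(20, params$v_reset,
                                 length.out = k_end - k_peak + 1L)
  }

  attach_stim <- if (!is.null(current_stim)) current_stim else mech_stim
  list(voltage = trace(v_out, dt = dt, kind = "voltage"),
       spikes = spike_train(spike_times, record_duration = tt[n],
                            stimulus = attach_stim))
}
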