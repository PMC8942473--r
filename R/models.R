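# Closed-form model curves shared by the synthetic generator and the
# fitting suite.

.kB <- 1.380649e-23  # Boltzmann constant, J/K

#' Boltzmann open-probability curve
#'
#' Single-state activation `p_o(X) = 1 / (1 + exp(-s * (X - x_half)))`
#' with positive slope `s`, so open probability grows with displacement
#' and equals 0.5 at `x_half`. The slope relates to the single-channel
#' gating force z through `s = z / (kT)` (with X in um and z in N,
#' `z = s * kB * T * 1e6`).
#'
#' @param x Displacement in um (vectorized).
#' @param x_half Half-activation displacement in um.
#' @param slope Slope factor s in 1/um (> 0).
#' @return Open probability in `(0, 1)`.
#' @export
boltzmann_po <- function(x, x_half, slope) {
  1 / (1 + exp(-slope * (x - x_half)))
}

# Two-component activation: weighted sum of two single-Boltzmann terms.
.boltzmann2_po <- function(x, x_half1, slope1, x_half2, slope2, w1) {
  w1 * boltzmann_po(x, x_half1, slope1) +
    (1 - w1) * boltzmann_po(x, x_half2, slope2)
}

#' Logistic (Hill) dose-response curve
#'
#' `I(C) = (I_i - I_f) / (1 + (C / c_half)^p) + I_f`, the standard Hill
#' block with half-blocking concentration `c_half` (the IC50) and Hill
#' coefficient `p`.
#'
#' @param conc Concentration in uM (vectorized).
#' @param i_initial Unblocked current amplitude `I_i` (pA).
#' @param i_final Residual current at saturating blocker `I_f` (pA).
#' @param c_half Half-blocking concentration (uM, > 0).
#' @param hill_p Hill coefficient (> 0).
#' @return Current amplitude in pA.
#' @export
hill_current <- function(conc, i_initial, i_final, c_half, hill_p = 1) {
  (i_initial - i_final) / (1 + (conc / c_half)^hill_p) + i_final
}

#' Fractional block at a given blocker concentration
#'
#' `B(C) = (C / c_half)^p / (1 + (C / c_half)^p)`, the fraction of the
#' blockable current suppressed at concentration `C` under the Hill model
#' with complete block at saturation.
#'
#' @inheritParams hill_current
#' @return Fraction blocked in `[0, 1)`.
#' @export
hill_block_fraction <- function(conc, c_half, hill_p = 1) {
  r <- (conc / c_half)^hill_p
  r / (1 + r)
}

#' Bi-exponential decay curve
#'
#' `y(t) = a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + a_ss`: two decaying
#' current components plus a steady-state, non-inactivating component.
#'
#' @param t Time in ms from the start of the decay (vectorized).
#' @param a1,a2 Component amplitudes (pA).
#' @param tau1,tau2 Time constants in ms (`tau1 < tau2`).
#' @param a_ss Steady-state amplitude (pA).
#' @return Current in pA.
#' @export
biexp_current <- function(t, a1, tau1, a2, tau2, a_ss) {
  a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + a_ss
}

#' Linear I-V curve
#'
#' `I(V) = g * (V - e_rev)` for an Ohmic conductance `g` (nS) with
#' reversal potential `e_rev` (mV); current in pA.
#'
#' @param v Membrane voltage in mV (vectorized).
#' @param conductance Slope conductance in nS.
#' @param e_rev Reversal potential in mV.
#' @return Current in pA.
#' @export
iv_current <- function(v, conductance, e_rev) {
  conductance * (v - e_rev)
}

#' Normalize peak currents to open probability
#'
#' Expresses a series of peak mechanically activated currents as open
#' probability by normalizing to the largest magnitude in the series,
#' `p_o = I(X) / max|I|`.
#'
#' @param i Peak currents (pA), one per displacement step.
#' @return Open-probability values in `[0, 1]` (by magnitude).
#' @export
po_from_peaks <- function(i) {
  m <- max(abs(i))
  if (m == 0) stop("all peak currents are zero", call. = FALSE)
  abs(i) / m
}
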