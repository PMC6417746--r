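#' Sodium activation steady state
#'
#' Boltzmann activation curve of the reduced sodium current,
#' `m_inf(V) = 1/(1 + exp(-(V - vhalf)/slope))`.  Activation is treated as
#' instantaneous (`m = m_inf(V2)`).  The half-activation voltage and slope
#' follow the Rothman-Manis lineage of auditory brainstem models and are
#' exposed so the activation curve can be recalibrated.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param vhalf Half-activation voltage, mV.
#' @param slope Slope factor, mV.
#' @return Activation in \[0, 1\].
#' @export
m_inf <- function(V, vhalf = -38, slope = 7) {
  1 / (1 + exp(-(V - vhalf) / slope))
}

#' Sodium inactivation gate: steady state and time constant
#'
#' `h_inf(V) = 1/(1 + exp((V + 65)/6))` (strictly decreasing) and
#' `tau_h(V) = 0.24 * (100/(7 exp((V+60)/11) + 10 exp(-(V+60)/25)) + 0.6)` ms
#' (kinetics at 35 degrees C).
#'
#' @param V Membrane potential, mV (vectorized).
#' @return A list with components `h_inf` and `tau_h` (ms).
#' @examples
#' h_gate(-65)$h_inf  # 0.5
#' @export
h_gate <- function(V) {
  list(h_inf = 1 / (1 + exp((V + 65) / 6)),
       tau_h = 0.24 * (100 / (7 * exp((V + 60) / 11) +
                                10 * exp(-(V + 60) / 25)) + 0.6))
}

#' KLT activation gate: steady state and time constant
#'
#' `w_inf(V) = 1/(1 + exp(-(V + 65)/6))` (strictly increasing, as required of
#' an activation gate that provides negative feedback on depolarization) and
#' `tau_w(V) = 0.46 * (100/(6 exp((V+75)/12.15) + 24 exp(-(V+75)/25)) + 0.55)`
#' ms (35 degrees C).
#'
#' @param V Membrane potential, mV (vectorized).
#' @return A list with components `w_inf` and `tau_w` (ms).
#' @examples
#' w_gate(-65)$w_inf  # 0.5
#' @export
w_gate <- function(V) {
  list(w_inf = 1 / (1 + exp(-(V + 65) / 6)),
       tau_w = 0.46 * (100 / (6 * exp((V + 75) / 12.15) +
                                24 * exp(-(V + 75) / 25)) + 0.55))
}

#' KLT inactivation steady state
#'
#' `z_inf(V) = 0.78/(1 + exp((V + 57)/5.44)) + 0.22`.  The inactivation gate
#' is slow (hundreds of ms) and is always held frozen at `z_inf(Vrest)` in the
#' model.
#'
#' @param V Membrane potential, mV (vectorized).
#' @return Steady-state inactivation in \[0.22, 1\].
#' @export
z_inf <- function(V) {
  0.78 / (1 + exp((V + 57) / 5.44)) + 0.22
}

#' Sodium current
#'
#' `I_Na = gna * m_inf(V2)^3 * h * (V2 - ENa)` minus the constant correction
#' term `gna * m_inf(Vrest)^3 * h_inf(Vrest) * (Vrest - ENa)`, so that the
#' current vanishes at rest and the resting potential is unchanged by adding
#' sodium conductance.
#'
#' @param V2 Axon-compartment potential, mV (vectorized).
#' @param h Inactivation gate value in \[0, 1\].
#' @param gna Maximal conductance, nS.
#' @param Vrest Resting potential, mV.
#' @param ENa Reversal potential, mV.
#' @param m_vhalf,m_slope Activation-curve parameters, see [m_inf()].
#' @return Current in pA (positive = outward).
#' @examples
#' na_current(-58, h_gate(-58)$h_inf, gna = 1000)  # 0 at rest
#' @export
na_current <- function(V2, h, gna, Vrest = -58, ENa = 55,
                       m_vhalf = -38, m_slope = 7) {
  stopifnot(all(h >= 0 & h <= 1))
  corr <- gna * m_inf(Vrest, m_vhalf, m_slope)^3 * h_gate(Vrest)$h_inf *
    (Vrest - ENa)
  gna * m_inf(V2, m_vhalf, m_slope)^3 * h * (V2 - ENa) - corr
}

#' Low-threshold potassium current
#'
#' `I_KLT = gklt * w^4 * z_inf(Vrest) * (V - EK)` minus the constant
#' correction term evaluated at rest (with `w = w_inf(Vrest)`), so that the
#' current vanishes at the resting potential.  The slow inactivation gate `z`
#' is always frozen at its resting value.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param w Activation gate value in \[0, 1\].
#' @param gklt Maximal conductance, nS.
#' @param Vrest Resting potential, mV.
#' @param EK Potassium reversal potential, mV.
#' @return Current in pA (positive = outward).
#' @examples
#' klt_current(-58, w_gate(-58)$w_inf, gklt = 50)  # 0 at rest
#' @export
klt_current <- function(V, w, gklt, Vrest = -58, EK = -106) {
  stopifnot(all(w >= 0 & w <= 1))
  zr <- z_inf(Vrest)
  corr <- gklt * w_gate(Vrest)$w_inf^4 * zr * (Vrest - EK)
  gklt * w^4 * zr * (V - EK) - corr
}

#' Split a leak conductance into leak plus KLT
#'
#' Replaces a fraction of a compartment's leak conductance with KLT
#' conductance while preserving the total conductance at rest exactly:
#' `g_leak_new = (1 - fraction) * g_lk` and
#' `g_klt = fraction * g_lk / (w_inf(Vrest)^4 * z_inf(Vrest))`, so that
#' `g_leak_new + g_klt * w_inf(Vrest)^4 * z_inf(Vrest) = g_lk`.
#'
#' @param g_lk Original leak conductance, nS.
#' @param fraction Fraction of `g_lk` carried by KLT at rest, in \[0, 1).
#' @param Vrest Resting potential, mV.
#' @return A list with components `g_leak` (nS) and `g_klt` (nS).
#' @examples
#' allocate_klt(100, 0.1)
#' @export
allocate_klt <- function(g_lk, fraction, Vrest = -58) {
  stopifnot(is.numeric(g_lk), g_lk >= 0, is.numeric(fraction))
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must lie in [0, 1)")
  rest_factor <- w_gate(Vrest)$w_inf^4 * z_inf(Vrest)
  list(g_leak = (1 - fraction) * g_lk,
       g_klt = fraction * g_lk / rest_factor)
}

#' Export gating curves as a table
#'
#' Tabulates the sodium and KLT gating steady states and time constants on a
#' voltage grid, e.g. for inspection or CSV export.
#'
#' @param V Voltage grid, mV.
#' @param m_vhalf,m_slope Sodium activation parameters, see [m_inf()].
#' @return A data frame with columns `V`, `m_inf`, `h_inf`, `tau_h`, `w_inf`,
#'   `tau_w`, `z_inf`.
#' @export
gating_table <- function(V = seq(-100, 40, by = 1), m_vhalf = -38,
                         m_slope = 7) {
  hg <- h_gate(V); wg <- w_gate(V)
  data.frame(V = V, m_inf = m_inf(V, m_vhalf, m_slope),
             h_inf = hg$h_inf, tau_h = hg$tau_h,
             w_inf = wg$w_inf, tau_w = wg$tau_w, z_inf = z_inf(V))
}
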