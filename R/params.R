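#' Izhikevich neuron parameters
#'
#' Constructs the parameter set of an Izhikevich adaptive quadratic
#' integrate-and-fire neuron in dimensional form: `C dv/dt = k (v - v_r)
#' (v - v_t) - u + I`, `du/dt = a (b (v - v_r) - u)`, with reset `v -> c`,
#' `u -> u + d` whenever `v >= v_peak`.
#'
#' @param C Membrane capacitance (pF).
#' @param k Sharpness of the quadratic nonlinearity (dimensionless).
#' @param v_r Resting potential (mV).
#' @param v_t Threshold potential (mV).
#' @param a Recovery rate (1/ms).
#' @param b Recovery sensitivity.
#' @param c Reset voltage (mV).
#' @param d Reset recovery increment.
#' @param v_peak Spike cutoff (mV).
#' @return A list of class `izhi_params`.
#' @export
izhikevich_params <- function(C, k, v_r, v_t, a, b, c, d, v_peak) {
  stopifnot(C > 0, a > 0, v_r < v_t, v_t < v_peak)
  structure(list(C = C, k = k, v_r = v_r, v_t = v_t, a = a, b = b,
                 c = c, d = d, v_peak = v_peak),
            class = "izhi_params")
}

#' Apical-compartment parameters
#'
#' Parameters of the nonlinear apical (dendritic) compartment of the L5
#' pyramidal-tract cell: `C dv/dt = -l (v - v_r) + g f(v) + m H(t - t_s) +
#' u + I`, `du/dt = a (b (v - v_r) - u)` with the regenerative calcium
#' nonlinearity `f(v) = 1 / (1 + exp(-(v + 38) / 6))`. The recovery
#' timescale is a time constant of 130 ms, i.e. `a = 1/130` per ms, and
#' `b < 0` makes the recovery variable hyperpolarizing. A back-propagating
#' action potential (bAP) contributes `+m` pA during a window delayed by
#' `bap_delay` after the somatic spike and lasting `bap_duration`.
#'
#' @param C Capacitance (pF).
#' @param l Leak conductance (nS).
#' @param g Amplitude of the regenerative nonlinearity (pA).
#' @param m bAP amplitude (pA).
#' @param v_r Resting potential (mV).
#' @param a Recovery rate (1/ms).
#' @param b Recovery sensitivity (nS, negative).
#' @param v_plateau_threshold Plateau detection threshold (mV); while the
#'   apical potential is above it the soma may adopt bursting resets.
#' @param bap_delay,bap_duration bAP window timing (ms).
#' @return A list of class `apical_params`.
#' @export
apical_params <- function(C = 170, l = 24.2857, g = 1200, m = 2600,
                          v_r = -70, a = 1 / 130, b = -13,
                          v_plateau_threshold = -30,
                          bap_delay = 0.5, bap_duration = 2) {
  stopifnot(C > 0, l > 0, g > 0, m >= 0, b < 0, a > 0)
  structure(list(C = C, l = l, g = g, m = m, v_r = v_r, a = a, b = b,
                 v_plateau_threshold = v_plateau_threshold,
                 bap_delay = bap_delay, bap_duration = bap_duration),
            class = "apical_params")
}

#' Regenerative calcium nonlinearity of the apical compartment
#'
#' Logistic activation with half-activation at -38 mV and slope 6 mV.
#'
#' @param v Membrane potential (mV).
#' @return Activation in (0, 1).
#' @export
apical_f <- function(v) 1 / (1 + exp(-(v + 38) / 6))

#' Default cell-class parameter bank
#'
#' The constants used throughout: the L5 pyramidal-tract soma carries two
#' reset pairs — regular spiking (RS: c = -65, d = 250) and intrinsic
#' bursting (IB: c = -55, d = 150); bursting raises the reset toward
#' threshold and reduces spike adaptation. Basket (fast-spiking
#' interneuron) and matrix-thalamus cells are single-regime.
#'
#' @return A list with elements `soma` (with `regimes`), `basket`,
#'   `thalamus` (`izhi_params`) and `apical` (`apical_params`).
#' @export
default_cell_params <- function() {
  soma <- izhikevich_params(C = 150, k = 2.5, v_r = -75, v_t = -45,
                            a = 0.01, b = 5, c = -65, d = 250, v_peak = 50)
  soma$regimes <- list(RS = list(c = -65, d = 250),
                       IB = list(c = -55, d = 150))
  list(
    soma = soma,
    basket = izhikevich_params(C = 20, k = 1, v_r = -55, v_t = -40,
                               a = 0.01, b = 8, c = -55, d = 200, v_peak = 25),
    thalamus = izhikevich_params(C = 200, k = 1.6, v_r = -60, v_t = -50,
                                 a = 0.01, b = 0.01, c = -60, d = 10,
                                 v_peak = 35),
    apical = apical_params()
  )
}

#' Synapse and drive constants
#'
#' Decay constants, reversal potentials, the NMDA conductance cap, the
#' thalamus-gated coupling time constant and the slow adaptation current
#' parameters.
#'
#' @return Named list of constants.
#' @export
default_synapse_params <- function() {
  list(
    tau_ampa = 6, tau_gaba = 6, tau_nmda = 100,       # ms
    E_exc = 0, E_inh = -75, E_adapt = -80,            # mV
    nmda_cap = 85,                                    # nS
    tau_coupling = 800,                               # ms
    tau_adapt = 2000, delta_g_adapt = 0.065           # ms, nS per spike
  )
}
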