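#' Poisson external spikes
#'
#' Independent Poisson spike counts per cell for one time step; mean count
#' is `rate * dt / 1000` for `rate` in Hz and `dt` in ms.
#'
#' @param rate Rate in Hz (scalar or per-cell vector).
#' @param dt Step (ms).
#' @param n_cells Number of cells.
#' @return Integer vector of counts.
#' @export
poisson_spikes <- function(rate, dt = 0.1, n_cells = length(rate)) {
  if (any(rate < 0)) stop("negative Poisson rate")
  stats::rpois(n_cells, rate * dt / 1000)
}

periodic_index_distance <- function(i, center, n) {
  d <- abs(i - center)
  pmin(d, n - d)
}

#' Spatial footprint of the whisker-deflection pulse
#'
#' Gaussian weight in index space, `exp(-(d / sigma)^2)` with periodic
#' ring distance `d = min(|i - N|, n - |i - N|)`. Multiplies the pulse
#' amplitude to give the current injected into each L5 soma during the
#' stimulus window.
#'
#' @param i Cell index (1-based, vectorised).
#' @param center Index of the pulse centre.
#' @param sigma Spatial spread (index units, default 20).
#' @param n Ring size.
#' @return Weight in `(0, 1]`.
#' @export
pulse_footprint <- function(i, center, sigma = 20, n = 90) {
  exp(-(periodic_index_distance(i, center, n) / sigma)^2)
}

#' Spatial footprints of the rivalry (monocular) drives
#'
#' Each eye's drive is an independent Poisson process whose per-cell rate
#' is the eye rate times a Gaussian footprint in index space (periodic
#' distance), centred on sites 90 degrees of orientation apart (45 sites
#' on a 90-site ring).
#'
#' @param i Cell index (1-based, vectorised).
#' @param center_left,center_right Centres of the two drives.
#' @param sigma Spatial spread (index units, default 18).
#' @param n Ring size.
#' @return A tibble with columns `i`, `left`, `right`.
#' @export
rivalry_footprint <- function(i, center_left = 23, center_right = 68,
                              sigma = 18, n = 90) {
  tibble::tibble(
    i = i,
    left = exp(-(periodic_index_distance(i, center_left, n) / sigma)^2),
    right = exp(-(periodic_index_distance(i, center_right, n) / sigma)^2)
  )
}

#' Slow adaptation conductance
#'
#' The somatic compartment of each L5 cell accumulates a slow
#' hyperpolarising conductance (a phenomenological calcium-activated
#' potassium current): decay constant 2000 ms, increment 0.065 nS per
#' somatic spike, reversal -80 mV. `step_adaptation()` advances one step;
#' `adaptation_current()` returns `g * (E_adapt - v)` in pA.
#'
#' @param g Adaptation conductance (nS).
#' @param spiked Logical/integer: spikes this step.
#' @param dt Step (ms).
#' @param tau Decay constant (ms).
#' @param delta_g Increment per spike (nS).
#' @return Updated conductance (nS).
#' @export
step_adaptation <- function(g, spiked, dt = 0.1, tau = 2000,
                            delta_g = 0.065) {
  g * exp(-dt / tau) + delta_g * as.numeric(spiked)
}

#' @rdname step_adaptation
#' @param v Membrane potential (mV).
#' @param E_adapt Reversal potential (mV).
#' @export
adaptation_current <- function(g, v, E_adapt = -80) g * (E_adapt - v)

#' Perturbation settings
#'
#' A constant current added for the whole run to either every apical
#' compartment or every thalamic cell in a mask: `side = "both"` targets
#' the full ring, `"left"`/`"right"` the 45 cortical sites centred on the
#' corresponding rivalry drive (thalamic cells are included when their
#' 9-cell block lies in the masked half). Positive amplitudes emulate
#' optogenetic excitation, negative ones pharmacological inhibition.
#'
#' @param target `"apical"` or `"thalamus"`.
#' @param side `"left"`, `"right"`, `"both"` or `"none"`.
#' @param amplitude Current (pA).
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target = c("apical", "thalamus"),
                              side = c("none", "left", "right", "both"),
                              amplitude = 0) {
  structure(list(target = match.arg(target), side = match.arg(side),
                 amplitude = amplitude),
            class = "perturbation_spec")
}

side_mask <- function(side, center_left = 23, center_right = 68, n = 90) {
  half <- n %/% 4          # 22 on a 90-ring: mask = centre +/- half, 45 sites
  center <- switch(side, left = center_left, right = center_right, NA)
  switch(side,
    none = rep(FALSE, n),
    both = rep(TRUE, n),
    (periodic_index_distance(seq_len(n), center, n) <= half)
  )
}

#' Per-cell perturbation currents
#'
#' Expands a [perturbation_spec()] into per-cell constant currents for the
#' apical compartments and the thalamic cells.
#'
#' @param spec A [perturbation_spec()].
#' @param geom A [ring_geometry()].
#' @param center_left,center_right Rivalry drive centres defining the
#'   half-ring masks.
#' @return List with numeric vectors `apical` (length `n_exc`) and
#'   `thalamus` (length `n_thal`).
#' @export
perturbation_currents <- function(spec, geom = ring_geometry(),
                                  center_left = 23, center_right = 68) {
  n <- geom$n_exc
  mask <- side_mask(spec$side, center_left, center_right, n)
  apical <- rep(0, n)
  thal <- rep(0, geom$n_thal)
  if (spec$target == "apical") {
    apical[mask] <- spec$amplitude
  } else {
    # a thalamic cell is perturbed when the majority of its block is masked
    in_mask <- tapply(mask, geom$thal_map, function(x) mean(x) > 0.5)
    thal[as.logical(in_mask)] <- spec$amplitude
  }
  list(apical = apical, thalamus = thal)
}

#' Drive settings
#'
#' Background and stimulus drives. Every somatic compartment (L5 somas,
#' baskets, thalamus) receives independent 600 Hz Poisson background and
#' every apical compartment 50 Hz, each external spike incrementing the
#' AMPA conductance by `w_ext`. `stim_kind = "pulse"` injects a 200 ms
#' current pulse of amplitude `pulse_amp` into L5 somas with a Gaussian
#' footprint (sigma 20) centred on `pulse_center`; `"rivalry"` adds two
#' independent Poisson drives (rates `rivalry_rates` Hz) with Gaussian
#' footprints (sigma 18) centred 45 sites apart.
#'
#' @param background_soma_rate,background_apical_rate Hz.
#' @param w_ext Conductance weight of one background spike onto L5 somas
#'   (nS).
#' @param w_ext_riv Weight of one monocular-drive spike onto L5 somas.
#' @param w_ext_basket,w_ext_apical Weights onto basket cells and apical
#'   compartments (default: same as `w_ext`).
#' @param w_ext_thal Weight of one external spike onto thalamic cells.
#'   The thalamic rheobase is tiny (40 pA), so full-weight background
#'   would make thalamus fire tonically and pin the soma-dendrite
#'   coupling near 1 on both sides; a weak thalamic background keeps
#'   baseline thalamic spiking sparse and lets coupling collapse in the
#'   suppressed population.
#' @param riv_nmda Monocular-drive spikes also increment the NMDA
#'   conductance.
#' @param ext_nmda External background spikes onto cortical targets also
#'   increment the NMDA conductance (with the same weight). Off by
#'   default: the calibrated baseline is AMPA fluctuation-driven, so the
#'   only slow NMDA components are recurrent and thalamo-dendritic —
#'   activity a population generates itself, which is what gives the
#'   dominant population its competitive advantage.
#' @param stim_kind `"none"`, `"pulse"` or `"rivalry"`.
#' @param pulse_amp Pulse amplitude (pA).
#' @param pulse_duration Pulse length (ms).
#' @param pulse_onset Pulse onset time (ms).
#' @param pulse_center Centre index.
#' @param sigma_td Pulse footprint spread.
#' @param rivalry_rates Length-2 rates (left, right) in Hz.
#' @param riv_right_onset Onset time (ms) of the right-eye drive (0 =
#'   simultaneous; later onsets support onset-asymmetry probes).
#' @param rivalry_centers Length-2 centre indices (45 sites apart).
#' @param sigma_vr Rivalry footprint spread.
#' @param background_in_rivalry Keep background drive on during rivalry.
#' @return A list of class `drive_spec`.
#' @export
drive_spec <- function(background_soma_rate = 600,
                       background_apical_rate = 50,
                       w_ext = 1.6, w_ext_basket = 0.34,
                       w_ext_apical = 1, w_ext_thal = 0.05,
                       w_ext_riv = 1.15, ext_nmda = FALSE,
                       riv_nmda = ext_nmda,
                       stim_kind = c("none", "pulse", "rivalry"),
                       pulse_amp = 0, pulse_duration = 200,
                       pulse_onset = 1500, pulse_center = 45, sigma_td = 20,
                       rivalry_rates = c(1400, 1400),
                       rivalry_centers = c(23, 68), sigma_vr = 18,
                       riv_right_onset = 0,
                       background_in_rivalry = TRUE) {
  stopifnot(background_soma_rate >= 0, background_apical_rate >= 0,
            pulse_amp >= 0, all(rivalry_rates >= 0))
  structure(list(
    background_soma_rate = background_soma_rate,
    background_apical_rate = background_apical_rate,
    w_ext = w_ext, w_ext_basket = w_ext_basket,
    w_ext_apical = w_ext_apical, w_ext_thal = w_ext_thal,
    w_ext_riv = w_ext_riv, ext_nmda = ext_nmda, riv_nmda = riv_nmda,
    stim_kind = match.arg(stim_kind),
    pulse_amp = pulse_amp, pulse_duration = pulse_duration,
    pulse_onset = pulse_onset, pulse_center = pulse_center,
    sigma_td = sigma_td,
    rivalry_rates = rivalry_rates, rivalry_centers = rivalry_centers,
    sigma_vr = sigma_vr, riv_right_onset = riv_right_onset,
    background_in_rivalry = background_in_rivalry
  ), class = "drive_spec")
}
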