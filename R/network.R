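#' Ring geometry
#'
#' Places `n_exc` excitatory/inhibitory cortical pairs at equidistant
#' angles on the unit circle. One full rotation of the ring spans 180
#' degrees of stimulus orientation, so neighbouring sites differ by
#' `180 / n_exc` degrees in orientation preference. The thalamic ring has
#' a 9:1 cortical:thalamic ratio; thalamic cell `t` receives from and
#' projects back to the block of 9 consecutive cortical cells
#' `9 (t - 1) + 1, ..., 9 t`.
#'
#' @param n_exc,n_inh,n_thal Population sizes.
#' @return A list of class `ring_geometry` with `angles` (radians) and
#'   `orientation_deg` per cortical site, and `thal_map` (thalamic partner
#'   index per cortical cell).
#' @export
ring_geometry <- function(n_exc = 90, n_inh = 90, n_thal = 10) {
  stopifnot(n_exc %% n_thal == 0, n_exc == n_inh)
  idx <- seq_len(n_exc) - 1L
  structure(list(
    n_exc = n_exc, n_inh = n_inh, n_thal = n_thal,
    block = n_exc %/% n_thal,
    angles = 2 * pi * idx / n_exc,
    orientation_deg = 180 * idx / n_exc,
    thal_map = (idx %/% (n_exc %/% n_thal)) + 1L
  ), class = "ring_geometry")
}

#' Euclidean chord distance between ring sites
#'
#' Distance between two points on the unit circle,
#' `sqrt((cos a - cos b)^2 + (sin a - sin b)^2)`, i.e. the chord length
#' `2 sin(|a - b| / 2)` in `[0, 2]`.
#'
#' @param theta_i,theta_j Angles in radians (vectorised).
#' @return Chord distance.
#' @export
ring_distance <- function(theta_i, theta_j) {
  sqrt((cos(theta_i) - cos(theta_j))^2 + (sin(theta_i) - sin(theta_j))^2)
}

#' Build the synaptic weight bank
#'
#' All-to-all circulant cortical weights with Gaussian spatial decay,
#' `w_ij = lambda * exp(-(d_ij / sigma)^2 / 2)` with `d_ij` the unit-circle
#' chord distance and `lambda = amp / (sigma * sqrt(2 pi))`, plus constant
#' block-wise thalamic wiring. Inhibition is spatially broader than
#' excitation (sigma 2 vs 0.5), producing centre-surround competition, and
#' its integrated strength exceeds the recurrent excitation so that two
#' competing stimulated populations fall into a winner-take-all regime
#' rather than a balanced coactive state; the default amplitudes are the
#' package's calibrated working point for that regime (see the methods
#' vignette for how they were chosen and for the narrower amplitude set,
#' `amp_ee_ampa = 6.125`, `amp_ee_nmda = 1.225`, `amp_ei = 1`,
#' `amp_ie = 5`, that parameterises a balanced, non-competitive network).
#' Cortico-thalamic weights are constant: E-to-TH 4 (AMPA),
#' TH-to-dendrite 10 (AMPA) and 10 (NMDA), within each 9-cell block only.
#'
#' @param geom A [ring_geometry()].
#' @param sigma_ee,sigma_ei,sigma_ie Spatial spreads (unit-circle scale).
#' @param amp_ee_ampa,amp_ee_nmda,amp_ei,amp_ie Raw amplitudes before the
#'   Gaussian normalisation.
#' @param w_e_th,w_th_d_ampa,w_th_d_nmda Constant thalamic weights.
#' @param self_connections Include distance-0 self weights (default TRUE;
#'   the cortical coupling is all-to-all).
#' @return A list of class `weight_bank` with matrices `W_ee_ampa`,
#'   `W_ee_nmda`, `W_ei`, `W_ie` (rows = postsynaptic, columns =
#'   presynaptic) and the thalamic scalars.
#' @export
build_weights <- function(geom = ring_geometry(),
                          sigma_ee = 0.5, sigma_ei = 2, sigma_ie = 2,
                          amp_ee_ampa = 7.79 * 6.125,
                          amp_ee_nmda = 1.33 * 1.225,
                          amp_ei = 0.85 * 2 * sqrt(2 * pi),
                          amp_ie = 6.27 * 2 * sqrt(2 * pi),
                          w_e_th = 4, w_th_d_ampa = 10, w_th_d_nmda = 10,
                          self_connections = TRUE) {
  d <- outer(geom$angles, geom$angles, ring_distance)
  gauss <- function(amp, sigma) {
    w <- amp / (sigma * sqrt(2 * pi)) * exp(-0.5 * (d / sigma)^2)
    if (!self_connections) diag(w) <- 0
    w
  }
  structure(list(
    W_ee_ampa = gauss(amp_ee_ampa, sigma_ee),
    W_ee_nmda = gauss(amp_ee_nmda, sigma_ee),
    W_ei = gauss(amp_ei, sigma_ei),
    W_ie = gauss(amp_ie, sigma_ie),
    w_e_th = w_e_th, w_th_d_ampa = w_th_d_ampa, w_th_d_nmda = w_th_d_nmda,
    thal_map = geom$thal_map
  ), class = "weight_bank")
}

#' NMDA voltage gate
#'
#' Voltage dependence of the NMDA conductance (magnesium-block relief):
#' `((v + 80)/60)^2 / (1 + ((v + 80)/60)^2)`. AMPA and GABA-A pathways use
#' a gate of 1.
#'
#' @param v Postsynaptic membrane potential (mV).
#' @return Gating factor in `[0, 1)`.
#' @export
nmda_gate <- function(v) {
  x <- ((v + 80) / 60)^2
  x / (1 + x)
}

#' Synaptic current
#'
#' `I = gate * g * (E_syn - v)` in pA for `g` in nS and voltages in mV;
#' depolarizing when `E_syn > v`.
#'
#' @param g Conductance (nS).
#' @param gate Voltage gate (1 for AMPA/GABA-A, [nmda_gate()] for NMDA).
#' @param E_syn Reversal potential (mV).
#' @param v Membrane potential (mV).
#' @return Current (pA).
#' @export
synaptic_current <- function(g, gate, E_syn, v) gate * g * (E_syn - v)

#' One conductance update step
#'
#' Exact exponential decay toward zero plus instantaneous jumps from the
#' summed presynaptic weight of this step's spikes. NMDA conductances are
#' clipped at the cap after the jump.
#'
#' @param g Conductance (nS).
#' @param tau Decay constant (ms).
#' @param weighted_spike_input Sum of presynaptic weights that fired.
#' @param dt Step (ms).
#' @param cap Optional upper clip (nS), e.g. 85 for NMDA.
#' @return Updated conductance (nS).
#' @export
step_conductance <- function(g, tau, weighted_spike_input = 0, dt = 0.1,
                             cap = Inf) {
  if (any(weighted_spike_input < 0)) stop("negative synaptic input weight")
  pmin(g * exp(-dt / tau) + weighted_spike_input, cap)
}

#' Export / import a weight bank as a tidy table
#'
#' One row per (presynaptic, postsynaptic, receptor) connection, including
#' the constant thalamic projections. `weights_from_table()` inverts the
#' export bit-exactly.
#'
#' @param bank A [build_weights()] bank.
#' @return A tibble with columns `pre_index`, `post_index`, `receptor`,
#'   `weight`.
#' @export
weights_to_table <- function(bank) {
  mat_tbl <- function(W, receptor) {
    tibble::tibble(
      pre_index = rep(seq_len(ncol(W)), each = nrow(W)),
      post_index = rep(seq_len(nrow(W)), times = ncol(W)),
      receptor = receptor,
      weight = as.vector(W)
    )
  }
  n <- nrow(bank$W_ee_ampa)
  thal <- tibble::tibble(
    pre_index = rep(seq_len(n), 3L),
    post_index = rep(bank$thal_map, 3L),
    receptor = rep(c("e_th_ampa", "th_d_ampa", "th_d_nmda"), each = n),
    weight = rep(c(bank$w_e_th, bank$w_th_d_ampa, bank$w_th_d_nmda), each = n)
  )
  # th_d rows run thalamus -> dendrite; store cortical cell as pre for those
  thal$pre_index[thal$receptor != "e_th_ampa"] <-
    rep(bank$thal_map, 2L)
  thal$post_index[thal$receptor != "e_th_ampa"] <-
    rep(seq_len(n), 2L)
  dplyr::bind_rows(
    mat_tbl(bank$W_ee_ampa, "ee_ampa"),
    mat_tbl(bank$W_ee_nmda, "ee_nmda"),
    mat_tbl(bank$W_ei, "ei"),
    mat_tbl(bank$W_ie, "ie"),
    thal
  )
}

#' @rdname weights_to_table
#' @param tbl A table produced by `weights_to_table()`.
#' @export
weights_from_table <- function(tbl) {
  get_mat <- function(receptor) {
    sub <- tbl[tbl$receptor == receptor, ]
    n <- max(sub$post_index)
    W <- matrix(0, n, max(sub$pre_index))
    W[cbind(sub$post_index, sub$pre_index)] <- sub$weight
    W
  }
  e_th <- tbl[tbl$receptor == "e_th_ampa", ]
  th_d_a <- tbl[tbl$receptor == "th_d_ampa", ]
  th_d_n <- tbl[tbl$receptor == "th_d_nmda", ]
  structure(list(
    W_ee_ampa = get_mat("ee_ampa"),
    W_ee_nmda = get_mat("ee_nmda"),
    W_ei = get_mat("ei"),
    W_ie = get_mat("ie"),
    w_e_th = e_th$weight[1],
    w_th_d_ampa = th_d_a$weight[1],
    w_th_d_nmda = th_d_n$weight[1],
    thal_map = e_th$post_index[order(e_th$pre_index)]
  ), class = "weight_bank")
}
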