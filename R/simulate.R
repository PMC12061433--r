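#' Run configuration
#'
#' Assembles everything a reproducible simulation needs: integration step,
#' duration, burn-in, drives, perturbation, geometry/weights and recording
#' options. All simulations default to the reference protocol: 0.1 ms
#' step, 30 s duration, 1 s burn-in discarded from statistics.
#'
#' @param dt Integration step (ms).
#' @param duration Simulated time (ms).
#' @param seed Integer seed; a run is bit-reproducible from (config, seed).
#' @param burn_in Initial interval (ms) excluded from statistics.
#' @param drive A [drive_spec()].
#' @param perturbation A [perturbation_spec()].
#' @param geometry A [ring_geometry()].
#' @param weights A [build_weights()] bank (built from `geometry` if NULL).
#' @param cells Cell parameter bank ([default_cell_params()]).
#' @param synapse Synapse constants ([default_synapse_params()]).
#' @param record_traces Record subsampled apical input current, regime
#'   flags and coupling per L5 cell.
#' @param record_every Trace subsampling (steps; default 10 = 1 ms).
#' @param noise_free Replace every Poisson drive with its mean-matched
#'   constant conductance increment (limit-cycle probe mode).
#' @param kick Optional probe kick: list with `amplitude` (pA),
#'   `onset`/`duration` (ms) and `side` ("left"/"right"/"both") applied to
#'   L5 somas.
#' @param init_v_offset Optional per-cell initial somatic depolarization
#'   (mV) to break symmetry in noise-free runs.
#' @param ee_to_apical Route recurrent E-to-E synapses onto the apical
#'   compartment instead of the soma (an alternative wiring in which
#'   recurrent excitation only benefits a population whose soma-dendrite
#'   coupling is intact). The default somatic routing is the calibrated
#'   working configuration.
#' @return A list of class `tc_config`.
#' @export
tc_config <- function(dt = 0.1, duration = 30000, seed = 1, burn_in = 1000,
                      drive = drive_spec(),
                      perturbation = perturbation_spec(),
                      geometry = ring_geometry(), weights = NULL,
                      cells = default_cell_params(),
                      synapse = default_synapse_params(),
                      record_traces = TRUE, record_every = 10L,
                      noise_free = FALSE, kick = NULL,
                      init_v_offset = NULL, ee_to_apical = FALSE) {
  stopifnot(dt > 0, duration >= burn_in)
  if (is.null(weights)) weights <- build_weights(geometry)
  structure(list(
    dt = dt, duration = duration, seed = seed, burn_in = burn_in,
    drive = drive, perturbation = perturbation,
    geometry = geometry, weights = weights, cells = cells,
    synapse = synapse, record_traces = record_traces,
    record_every = as.integer(record_every),
    noise_free = noise_free, kick = kick, init_v_offset = init_v_offset,
    ee_to_apical = ee_to_apical
  ), class = "tc_config")
}

build_engine_config <- function(config) {
  geom <- config$geometry
  drv <- config$drive
  n <- geom$n_exc
  idx <- seq_len(n)
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))

  soma <- config$cells$soma
  soma_l <- list(C = soma$C, k = soma$k, v_r = soma$v_r, v_t = soma$v_t,
                 a = soma$a, b = soma$b, v_peak = soma$v_peak,
                 c_rs = soma$regimes$RS$c, d_rs = soma$regimes$RS$d,
                 c_ib = soma$regimes$IB$c, d_ib = soma$regimes$IB$d)
  ap <- config$cells$apical
  ap_l <- list(C = ap$C, l = ap$l, g = ap$g, m = ap$m, v_r = ap$v_r,
               a = ap$a, b = ap$b,
               v_plateau_threshold = ap$v_plateau_threshold,
               bap_delay_steps = as.integer(round(ap$bap_delay / dt)),
               bap_duration_steps = as.integer(round(ap$bap_duration / dt)))

  lam <- function(rate_hz) rep(rate_hz, length.out = n) * dt / 1000
  riv_on <- drv$stim_kind == "rivalry"
  bg_on <- !riv_on || drv$background_in_rivalry
  fp <- rivalry_footprint(idx, drv$rivalry_centers[1], drv$rivalry_centers[2],
                          drv$sigma_vr, n)

  pulse_cell <- rep(0, n)
  pulse_on_step <- -1L; pulse_off_step <- -1L
  if (drv$stim_kind == "pulse" && drv$pulse_amp > 0) {
    pulse_cell <- drv$pulse_amp *
      pulse_footprint(idx, drv$pulse_center, drv$sigma_td, n)
    pulse_on_step <- as.integer(round(drv$pulse_onset / dt))
    pulse_off_step <- as.integer(round((drv$pulse_onset + drv$pulse_duration) / dt))
  }

  pert <- perturbation_currents(config$perturbation, geom,
                                drv$rivalry_centers[1], drv$rivalry_centers[2])

  kick_cell <- rep(0, n); kick_on <- -1L; kick_off <- -1L
  if (!is.null(config$kick)) {
    k <- config$kick
    mask <- side_mask(k$side %||% "left", drv$rivalry_centers[1],
                      drv$rivalry_centers[2], n)
    kick_cell[mask] <- k$amplitude
    kick_on <- as.integer(round(k$onset / dt))
    kick_off <- as.integer(round((k$onset + k$duration) / dt))
  }

  init_off <- config$init_v_offset %||% rep(0, n)

  wb <- config$weights
  list(
    n_exc = n, n_inh = geom$n_inh, n_thal = geom$n_thal,
    n_steps = n_steps, dt = dt, record_every = config$record_every,
    burn_steps = as.integer(round(config$burn_in / dt)),
    noise_free = config$noise_free, record_traces = config$record_traces,
    soma = soma_l, basket = config$cells$basket,
    thalamus = config$cells$thalamus, apical = ap_l,
    synapse = config$synapse,
    W_ee_ampa = wb$W_ee_ampa, W_ee_nmda = wb$W_ee_nmda,
    W_ei = wb$W_ei, W_ie = wb$W_ie,
    w_e_th = wb$w_e_th, w_th_d_ampa = wb$w_th_d_ampa,
    w_th_d_nmda = wb$w_th_d_nmda,
    thal_map = as.integer(geom$thal_map - 1L),
    lam_soma = if (bg_on) lam(drv$background_soma_rate) else lam(0),
    lam_basket = if (bg_on) rep(drv$background_soma_rate * dt / 1000, geom$n_inh)
                 else rep(0, geom$n_inh),
    lam_thal = if (bg_on) rep(drv$background_soma_rate * dt / 1000, geom$n_thal)
               else rep(0, geom$n_thal),
    lam_apical = if (bg_on) lam(drv$background_apical_rate) else lam(0),
    lam_riv_left = if (riv_on) drv$rivalry_rates[1] * fp$left * dt / 1000 else rep(0, n),
    lam_riv_right = if (riv_on) drv$rivalry_rates[2] * fp$right * dt / 1000 else rep(0, n),
    w_ext = drv$w_ext, w_ext_basket = drv$w_ext_basket,
    w_ext_apical = drv$w_ext_apical, w_ext_thal = drv$w_ext_thal,
    w_ext_riv = drv$w_ext_riv, ext_nmda = drv$ext_nmda,
    riv_nmda = drv$riv_nmda,
    pulse_amp_cell = pulse_cell, pulse_on_step = pulse_on_step,
    pulse_off_step = pulse_off_step,
    pert_apical = pert$apical, pert_thal = pert$thalamus,
    kick_amp_cell = kick_cell, kick_on_step = kick_on, kick_off_step = kick_off,
    init_v_offset = init_off,
    riv_right_on_step = as.integer(round((drv$riv_right_onset %||% 0) / dt)),
    ee_to_apical = config$ee_to_apical
  )
}

#' Run one network simulation
#'
#' Advances the full thalamocortical network for `config$duration` ms and
#' returns a recording: all spike events as a tidy table plus (optionally)
#' subsampled per-cell traces of the apical input current (every term of
#' the apical equation except the recovery variable — the quantity whose
#' distance to the first saddle-node current is analysed), the somatic
#' reset regime (RS/IB) and the thalamus-gated coupling variable.
#' Deterministic: two calls with the same config produce bit-identical
#' recordings.
#'
#' @param config A [tc_config()].
#' @param seed Overrides `config$seed` if given.
#' @return A list of class `tc_recording` with elements `spikes` (tibble:
#'   `population`, `cell`, `time_ms`), `traces` (list of matrices, rows =
#'   recorded times), `ei_balance`, `config`, `seed`.
#' @export
run_simulation <- function(config = tc_config(), seed = NULL) {
  seed <- seed %||% config$seed
  ecfg <- build_engine_config(config)
  set.seed(seed)
  raw <- simulate_tc_cpp(ecfg)
  spikes <- tibble::tibble(
    population = rep(c("exc", "inh", "thal"),
                     c(length(raw$exc_cell), length(raw$inh_cell),
                       length(raw$thal_cell))),
    cell = c(raw$exc_cell, raw$inh_cell, raw$thal_cell) + 1L,
    time_ms = c(raw$exc_time, raw$inh_time, raw$thal_time)
  )
  traces <- NULL
  if (config$record_traces) {
    traces <- list(time_ms = raw$trace_time,
                   apical_input = raw$apical_input,
                   regime = raw$regime,
                   coupling = raw$coupling)
  }
  structure(list(
    spikes = spikes, traces = traces,
    ei_balance = c(exc = raw$mean_exc_current, inh = raw$mean_inh_current,
                   g_exc = raw$mean_exc_conductance,
                   g_inh = raw$mean_inh_conductance),
    conductance_bounds = c(max_nmda = raw$max_nmda_conductance,
                           min_g = raw$min_conductance),
    config = config, seed = seed
  ), class = "tc_recording")
}

#' Run a batch of simulations over seeds
#'
#' @param config A [tc_config()].
#' @param seeds Integer vector of seeds.
#' @param map_fn Optional function applied to each recording immediately
#'   (so full traces need not be held for every seed at once); the batch
#'   then returns the list of its results.
#' @return List of `tc_recording`s (or of `map_fn` results).
#' @export
run_batch <- function(config, seeds, map_fn = NULL) {
  stopifnot(length(seeds) >= 1)
  purrr::map(seeds, function(s) {
    rec <- run_simulation(config, seed = s)
    if (is.null(map_fn)) rec else map_fn(rec)
  })
}

#' @export
print.tc_recording <- function(x, ...) {
  cat("<tc_recording> ", x$config$duration, " ms, seed ", x$seed, "\n", sep = "")
  counts <- dplyr::count(x$spikes, .data$population)
  for (i in seq_len(nrow(counts)))
    cat("  ", counts$population[i], ": ", counts$n[i], " spikes\n", sep = "")
  invisible(x)
}

#' Persist / reload a recording
#'
#' Spike events go to a CSV table (`population`, `cell`, `time_ms`) and the
#' run metadata (seed, duration, dt, burn-in, drive kind) to a JSON
#' sidecar. The event round trip is lossless; traces are regenerable from
#' (config, seed) by the determinism contract.
#'
#' @param recording A `tc_recording`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly (`write`); a list with `spikes` and `meta`
#'   (`read`).
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(recording$spikes, path)
  meta <- list(seed = recording$seed, dt = recording$config$dt,
               duration = recording$config$duration,
               burn_in = recording$config$burn_in,
               stim_kind = recording$config$drive$stim_kind)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @param path CSV path written by `write_recording()`.
#' @export
read_recording <- function(path) {
  spikes <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              population = readr::col_character(),
                              cell = readr::col_integer(),
                              time_ms = readr::col_double()))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  list(spikes = tibble::as_tibble(spikes), meta = meta)
}
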