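#' Per-run rivalry analysis
#'
#' Convenience wrapper used by the rivalry protocols: smoothed side rates,
#' dominance periods (burn-in excluded), and, when the recording carries
#' traces, the dominant-side regime summaries.
#'
#' @param recording A `tc_recording` from a rivalry run.
#' @param kernel_ms Rate-smoothing boxcar (ms).
#' @param threshold_hz,min_duration_ms Dominance rule.
#' @return List with `periods`, `minutes` (analysed simulated minutes),
#'   `dominant_means` (NULL without traces), `seed`.
#' @export
analyze_rivalry_run <- function(recording, kernel_ms = 100,
                                threshold_hz = 5, min_duration_ms = 250) {
  cfg <- recording$config
  centers <- cfg$drive$rivalry_centers
  n <- cfg$geometry$n_exc
  left_cells <- which(side_mask("left", centers[1], centers[2], n))
  right_cells <- which(side_mask("right", centers[1], centers[2], n))
  rl <- population_rate(recording$spikes, left_cells, cfg$duration,
                        kernel_ms = kernel_ms)
  rr <- population_rate(recording$spikes, right_cells, cfg$duration,
                        kernel_ms = kernel_ms)
  keep <- rl$time_ms > cfg$burn_in
  periods <- detect_dominance(rl$rate_hz[keep], rr$rate_hz[keep],
                              time_ms = rl$time_ms[keep],
                              threshold_hz = threshold_hz,
                              min_duration_ms = min_duration_ms)
  dom <- NULL
  if (!is.null(recording$traces) && nrow(periods) > 0) {
    dom <- regime_summaries(recording, left_cells, right_cells,
                            periods)$dominant_means
  }
  list(periods = periods,
       minutes = (cfg$duration - cfg$burn_in) / 60000,
       dominant_means = dom,
       seed = recording$seed)
}

rivalry_config <- function(rates, seed = 1, duration = 30000,
                           perturbation = perturbation_spec(),
                           record_traces = TRUE, ...) {
  tc_config(duration = duration, seed = seed,
            drive = drive_spec(stim_kind = "rivalry", rivalry_rates = rates),
            perturbation = perturbation,
            record_traces = record_traces, ...)
}

#' Rivalry batch over seeds
#'
#' Runs one rivalry condition over several seeds, analysing each run as it
#' completes (traces are not accumulated).
#'
#' @param rates Length-2 monocular drive rates (Hz).
#' @param seeds Seeds.
#' @param duration Run length (ms).
#' @param perturbation A [perturbation_spec()].
#' @param record_traces Needed for the regime summaries; disable for pure
#'   duration statistics.
#' @return Tibble: one row per seed with `seed`, `n_periods`,
#'   `mean_duration_s`, `mean_duration_left_s`, `mean_duration_right_s`,
#'   `alternations_per_min`, regime means (NA without traces), plus a
#'   list-column `periods`.
#' @export
run_rivalry_batch <- function(rates, seeds, duration = 30000,
                              perturbation = perturbation_spec(),
                              record_traces = TRUE) {
  cfg <- rivalry_config(rates, perturbation = perturbation,
                        duration = duration, record_traces = record_traces)
  res <- run_batch(cfg, seeds, map_fn = analyze_rivalry_run)
  purrr::map_dfr(res, function(r) {
    p <- r$periods
    st <- duration_stats(p, total_minutes = r$minutes, fit = FALSE)
    side_mean <- function(s) {
      d <- p$duration_ms[p$side == s]
      if (length(d)) mean(d) / 1000 else NA_real_
    }
    dm <- r$dominant_means
    tibble::tibble(
      seed = r$seed, n_periods = nrow(p),
      mean_duration_s = if (nrow(p)) mean(p$duration_ms) / 1000 else NA_real_,
      mean_duration_left_s = side_mean("left"),
      mean_duration_right_s = side_mean("right"),
      alternations_per_min = st$alternations_per_min,
      burst_fraction = dm$burst_fraction %||% NA_real_,
      above_b1_fraction = dm$above_b1_fraction %||% NA_real_,
      mean_coupling = dm$mean_coupling %||% NA_real_,
      mean_distance_pa = dm$mean_distance_pa %||% NA_real_,
      periods = list(p)
    )
  })
}

#' Threshold-detection experiment
#'
#' Simulates the whisker-deflection detection protocol: on each trial the
#' network receives background drive and (except at intensity 0) a 200 ms
#' current pulse with Gaussian spatial footprint; the readout is the total
#' L5 somatic spike count in the 1000 ms window from pulse onset. The
#' control arm determines the optimal criterion, which perturbation arms
#' reuse. Per arm, the response probabilities are fitted with the
#' four-parameter psychometric function and summarised mechanistically
#' (mean distance-to-B1, burst fraction and coupling in the response
#' window, averaged across intensities).
#'
#' @param intensities Pulse amplitudes (pA); must include 0.
#' @param seeds One trial per seed per intensity per arm.
#' @param arms Named list of [perturbation_spec()]s; must include
#'   `control`.
#' @param trial_duration Trial length (ms).
#' @param pulse_onset Stimulus onset (ms).
#' @param window_ms Response window after onset (ms).
#' @return List of class `detection_result`: `counts` (tibble: arm,
#'   intensity, seed, count, mechanism summaries), `criterion`,
#'   `response` (tibble: arm, intensity, p_response), `fits` (named list
#'   of `psychfit`), `neurometric` (tibble per arm), `mechanism` (tibble
#'   per arm averaged across intensities).
#' @export
run_threshold_detection <- function(
    intensities = c(0, 50, 100, 150, 200, 250, 300, 350),
    seeds = 1:30,
    arms = list(
      control = perturbation_spec("apical", "none", 0),
      apical_exc = perturbation_spec("apical", "both", 300),
      apical_inh = perturbation_spec("apical", "both", -300),
      thalamus_inh = perturbation_spec("thalamus", "both", -300)
    ),
    trial_duration = 2500, pulse_onset = 1200, window_ms = 1000) {
  stopifnot(0 %in% intensities, "control" %in% names(arms))
  I_B1 <- bifurcation_points()$I_B1

  one_trial <- function(arm_name, pert, intensity, seed) {
    cfg <- tc_config(
      duration = trial_duration, seed = seed, burn_in = pulse_onset,
      drive = drive_spec(stim_kind = if (intensity > 0) "pulse" else "none",
                         pulse_amp = intensity, pulse_onset = pulse_onset),
      perturbation = pert, record_traces = TRUE, record_every = 50L)
    rec <- run_simulation(cfg)
    in_win <- rec$spikes$population == "exc" &
      rec$spikes$time_ms >= pulse_onset &
      rec$spikes$time_ms < pulse_onset + window_ms
    tr <- rec$traces
    twin <- tr$time_ms >= pulse_onset & tr$time_ms < pulse_onset + window_ms
    tibble::tibble(
      arm = arm_name, intensity = intensity, seed = seed,
      count = sum(in_win),
      mean_distance_pa = mean(tr$apical_input[twin, ]) - I_B1,
      burst_fraction = mean(tr$regime[twin, ]),
      mean_coupling = mean(tr$coupling[twin, ])
    )
  }

  grid <- tidyr::expand_grid(arm = names(arms), intensity = intensities,
                             seed = seeds)
  counts <- purrr::pmap_dfr(grid, function(arm, intensity, seed) {
    one_trial(arm, arms[[arm]], intensity, seed)
  })

  criterion <- optimal_criterion(counts[counts$arm == "control",
                                        c("intensity", "count")])
  response <- counts |>
    dplyr::group_by(.data$arm, .data$intensity) |>
    dplyr::summarise(p_response = mean(.data$count > criterion),
                     .groups = "drop")
  fits <- purrr::map(split(response, response$arm), fit_psychometric)
  neuro <- purrr::map_dfr(split(counts, counts$arm), function(d) {
    dplyr::mutate(neurometric(d[, c("intensity", "count")]), arm = d$arm[1])
  })
  mechanism <- counts |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(mean_distance_pa = mean(.data$mean_distance_pa),
                     burst_fraction = mean(.data$burst_fraction),
                     mean_coupling = mean(.data$mean_coupling),
                     mean_count = mean(.data$count), .groups = "drop")
  structure(list(counts = counts, criterion = criterion, response = response,
                 fits = fits, neurometric = neuro, mechanism = mechanism),
            class = "detection_result")
}

#' Levelt protocols
#'
#' Proposition 2: one drive fixed at 1400 Hz, the other decreased from
#' 1400 to 1250 Hz in 50 Hz steps; reports mean dominance duration of the
#' fixed-drive (stronger) and varied-drive (weaker) sides per condition.
#' Proposition 4: both drives swept together from 1300 to 1500 Hz;
#' reports alternations per minute per condition.
#'
#' @param proposition 2 or 4.
#' @param seeds Seeds per condition.
#' @param conditions Optional rate vector overriding the default sweep
#'   (varied-side rates for proposition 2, common rates for 4).
#' @param duration Run length (ms).
#' @return Tibble: one row per condition x seed (list-column `periods`
#'   retained), with condition columns `rate_fixed`/`rate_varied` (prop 2)
#'   or `rate_common` (prop 4).
#' @export
run_levelt <- function(proposition = c(2, 4), seeds = 1:30,
                       conditions = NULL, duration = 30000) {
  proposition <- match.arg(as.character(proposition[1]), c("2", "4"))
  if (proposition == "2") {
    varied <- conditions %||% seq(1400, 1250, by = -50)
    purrr::map_dfr(varied, function(rv) {
      res <- run_rivalry_batch(c(1400, rv), seeds, duration = duration,
                               record_traces = FALSE)
      dplyr::mutate(res, rate_fixed = 1400, rate_varied = rv,
                    .before = 1)
    })
  } else {
    common <- conditions %||% seq(1300, 1500, by = 50)
    purrr::map_dfr(common, function(rc) {
      res <- run_rivalry_batch(c(rc, rc), seeds, duration = duration,
                               record_traces = FALSE)
      dplyr::mutate(res, rate_common = rc, .before = 1)
    })
  }
}

#' Rivalry perturbation experiments
#'
#' Asymmetric (`"asym"`): the perturbation targets the half-ring of the
#' left drive; reports perturbed- vs unperturbed-side dominance durations
#' per arm. Symmetric (`"sym"`): the whole ring is perturbed; reports
#' alternation rates. Both include the regime summaries of the dominant
#' population.
#'
#' @param symmetry `"asym"` or `"sym"`.
#' @param seeds Seeds per arm.
#' @param arms Named list of [perturbation_spec()]s (a `control` arm with
#'   amplitude 0 is always added).
#' @param rates Monocular drive rates.
#' @param duration Run length (ms).
#' @return Tibble: one row per arm x seed with the [run_rivalry_batch()]
#'   columns plus `arm`.
#' @export
run_rivalry_perturbation <- function(
    symmetry = c("asym", "sym"), seeds = 1:30,
    arms = NULL, rates = c(1400, 1400), duration = 30000) {
  symmetry <- match.arg(symmetry)
  side <- if (symmetry == "asym") "left" else "both"
  arms <- arms %||% list(
    apical_exc_400 = perturbation_spec("apical", side, 400),
    apical_exc_200 = perturbation_spec("apical", side, 200),
    apical_inh_200 = perturbation_spec("apical", side, -200),
    apical_inh_400 = perturbation_spec("apical", side, -400),
    thalamus_inh_200 = perturbation_spec("thalamus", side, -200),
    thalamus_inh_400 = perturbation_spec("thalamus", side, -400)
  )
  arms <- c(list(control = perturbation_spec("apical", "none", 0)), arms)
  purrr::imap_dfr(arms, function(pert, arm_name) {
    res <- run_rivalry_batch(rates, seeds, duration = duration,
                             perturbation = pert)
    dplyr::mutate(res, arm = arm_name, .before = 1)
  })
}

#' Noise-free limit-cycle probe
#'
#' Replaces every Poisson drive by its mean-matched constant conductance
#' increment and runs three rivalry simulations: (1) asymmetric initial
#' conditions, no kick; (2) symmetric initial conditions with a brief
#' somatic current kick to one half-ring; (3) asymmetric initial
#' conditions with the same kick. Sustained post-kick alternation in (2)
#' and its persistence in (3) indicate a stable limit cycle surrounding
#' the symmetric state.
#'
#' @param rates Monocular drive rates (Hz).
#' @param duration Run length (ms).
#' @param kick_time,kick_amplitude,kick_duration Probe kick (ms, pA, ms).
#' @param init_offset_mv Somatic depolarization of the left half-ring used
#'   for asymmetric initial conditions.
#' @param seed Seed (regime/bAP gating draws remain stochastic).
#' @return Tibble: one row per probe run with `probe`, `n_periods`,
#'   `alternations_per_min`, `alternating_after_kick` and list-column
#'   `periods`.
#' @export
run_limit_cycle_probe <- function(rates = c(1400, 1400), duration = 15000,
                                  kick_time = 5000, kick_amplitude = 200,
                                  kick_duration = 50, init_offset_mv = 5,
                                  seed = 1) {
  n <- 90
  asym <- rep(0, n); asym[side_mask("left", 23, 68, n)] <- init_offset_mv
  kick <- list(amplitude = kick_amplitude, onset = kick_time,
               duration = kick_duration, side = "left")
  probes <- list(
    asym_no_kick = list(init = asym, kick = NULL),
    sym_kick = list(init = NULL, kick = kick),
    asym_kick = list(init = asym, kick = kick)
  )
  purrr::imap_dfr(probes, function(p, name) {
    cfg <- tc_config(duration = duration, seed = seed,
                     drive = drive_spec(stim_kind = "rivalry",
                                        rivalry_rates = rates),
                     noise_free = TRUE, kick = p$kick,
                     init_v_offset = p$init, record_traces = FALSE)
    rec <- run_simulation(cfg)
    an <- analyze_rivalry_run(rec)
    post <- an$periods[an$periods$start_ms > kick_time, ]
    tibble::tibble(
      probe = name, n_periods = nrow(an$periods),
      alternations_per_min = duration_stats(an$periods,
                                            an$minutes, fit = FALSE)$alternations_per_min,
      alternating_after_kick = nrow(post) >= 2 &&
        length(unique(post$side)) == 2,
      periods = list(an$periods)
    )
  })
}

#' Synthetic fixtures for analysis-stack tests
#'
#' Deterministic toy inputs with known ground truth: `"durations"` draws
#' Gamma(4.85, scale 0.56) samples; `"rates"` builds a rate-trace pair
#' with exactly three constructed dominance periods (left 2 s, right 1 s,
#' left 1.5 s separated by sub-threshold gaps); `"detection"` generates
#' binomial responses from the four-parameter psychometric function at
#' (alpha 150, beta 0.05, lambda 0.05, gamma 0.1).
#'
#' @param kind `"durations"`, `"rates"` or `"detection"`.
#' @param n Sample count (durations: draws; detection: trials per level).
#' @param seed Seed.
#' @return Kind-specific: numeric vector, list of rate tibbles, or tibble
#'   with `intensity`, `n`, `p_response`, `true_par`.
#' @export
make_fixtures <- function(kind = c("durations", "rates", "detection"),
                          n = 1000, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    durations = stats::rgamma(n, shape = 4.85, scale = 0.56),
    rates = {
      t_ms <- seq(1, 6000)
      left <- rep(2, length(t_ms)); right <- rep(2, length(t_ms))
      left[t_ms <= 2000] <- 20                   # left dominant 2 s
      right[t_ms > 2500 & t_ms <= 3500] <- 20    # right dominant 1 s
      left[t_ms > 4000 & t_ms <= 5500] <- 20     # left dominant 1.5 s
      list(time_ms = t_ms,
           left = tibble::tibble(time_ms = t_ms, rate_hz = left),
           right = tibble::tibble(time_ms = t_ms, rate_hz = right),
           true_periods = tibble::tibble(
             side = c("left", "right", "left"),
             duration_ms = c(2000, 1000, 1500)))
    },
    detection = {
      true_par <- list(alpha = 150, beta = 0.05, lambda = 0.05, gamma = 0.1)
      x <- seq(0, 350, by = 50)
      p <- psychometric_fun(x, true_par$alpha, true_par$beta,
                            true_par$lambda, true_par$gamma)
      tibble::tibble(intensity = x, n = n,
                     p_response = stats::rbinom(length(x), n, p) / n,
                     true_p = p) |>
        structure(true_par = true_par)
    })
}
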