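#' Inter-spike-interval coefficient of variation
#'
#' CV = sd(ISI)/mean(ISI) per cell (cells with at least 3 spikes after the
#' burn-in), averaged across cells. Values near 1 indicate Poisson-like
#' irregularity; bursting pushes the CV well above 1.
#'
#' @param spikes Spike tibble (`population`, `cell`, `time_ms`).
#' @param population Which population to use (default `"exc"`).
#' @param burn_in Discard spikes before this time (ms).
#' @return Population-mean CV (scalar).
#' @export
isi_cv <- function(spikes, population = "exc", burn_in = 0) {
  s <- spikes[spikes$population == population & spikes$time_ms >= burn_in, ]
  if (nrow(s) == 0) stop("no spikes in population '", population, "'")
  per_cell <- s |>
    dplyr::group_by(.data$cell) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(cv = {
      isi <- diff(sort(.data$time_ms))
      stats::sd(isi) / mean(isi)
    }, .groups = "drop")
  if (nrow(per_cell) == 0) stop("no cell has >= 3 spikes")
  mean(per_cell$cv)
}

#' Smoothed population firing rate
#'
#' Bins the spikes of the masked cells at `bin_ms`, smooths with a causal
#' boxcar of length `kernel_ms`, and converts to a per-cell rate in Hz.
#'
#' @param spikes Spike tibble.
#' @param cells Cell indices included in the average.
#' @param t_max Duration covered (ms).
#' @param population Population name.
#' @param bin_ms Bin width (ms).
#' @param kernel_ms Causal boxcar length (ms).
#' @return Tibble with `time_ms` (bin end) and `rate_hz`.
#' @export
population_rate <- function(spikes, cells, t_max, population = "exc",
                            bin_ms = 1, kernel_ms = 100) {
  if (length(cells) == 0) stop("empty cell mask")
  s <- spikes[spikes$population == population & spikes$cell %in% cells, ]
  n_bins <- ceiling(t_max / bin_ms)
  counts <- tabulate(pmin(floor(s$time_ms / bin_ms) + 1L, n_bins), n_bins)
  k <- max(1L, round(kernel_ms / bin_ms))
  # causal boxcar: average of the current and previous k-1 bins
  smoothed <- stats::filter(counts, rep(1 / k, k), sides = 1)
  smoothed[is.na(smoothed)] <- cumsum(counts)[seq_len(k - 1)] / seq_len(k - 1)
  tibble::tibble(
    time_ms = seq_len(n_bins) * bin_ms,
    rate_hz = as.numeric(smoothed) / length(cells) / (bin_ms / 1000)
  )
}

#' Detect perceptual dominance periods
#'
#' A population is dominant while its smoothed rate exceeds the
#' competitor's by strictly more than `threshold_hz`; contiguous intervals
#' shorter than `min_duration_ms` are discarded. Gaps count as no
#' dominance.
#'
#' @param rate_left,rate_right Equal-length rate traces (Hz), as from
#'   [population_rate()] (vectors or tibbles with `rate_hz`).
#' @param time_ms Bin times (taken from `rate_left` if it is a tibble).
#' @param threshold_hz Dominance threshold (Hz, strict).
#' @param min_duration_ms Minimum period length (ms).
#' @return Tibble with `side` ("left"/"right"), `start_ms`, `end_ms`,
#'   `duration_ms`.
#' @export
detect_dominance <- function(rate_left, rate_right, time_ms = NULL,
                             threshold_hz = 5, min_duration_ms = 250) {
  if (is.data.frame(rate_left)) {
    time_ms <- time_ms %||% rate_left$time_ms
    rate_left <- rate_left$rate_hz
  }
  if (is.data.frame(rate_right)) rate_right <- rate_right$rate_hz
  stopifnot(length(rate_left) == length(rate_right))
  if (is.null(time_ms)) time_ms <- seq_along(rate_left)
  diffr <- rate_left - rate_right
  state <- ifelse(diffr > threshold_hz, 1L, ifelse(diffr < -threshold_hz, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  out <- tibble::tibble(
    side = ifelse(r$values[keep] == 1L, "left", "right"),
    start_ms = time_ms[starts[keep]],
    end_ms = time_ms[ends[keep]]
  )
  out$duration_ms <- out$end_ms - out$start_ms +
    (if (length(time_ms) > 1) diff(time_ms)[1] else 1)
  out[out$duration_ms >= min_duration_ms, ]
}

#' Dominance-duration statistics and distribution fits
#'
#' Durations in seconds, the alternation rate (side switches between
#' successive dominance periods per simulated minute) and maximum-
#' likelihood fits of Gamma, lognormal and normal distributions compared
#' by mean per-sample negative log likelihood.
#'
#' @param periods Dominance tibble from [detect_dominance()] (pooled
#'   across seeds is fine for the fits).
#' @param total_minutes Simulated minutes underlying `periods` (after
#'   burn-in); needed for the alternation rate.
#' @param fit Fit the three candidate distributions (needs >= 20 samples
#'   to be flagged reliable).
#' @return A list of class `dominance_stats`: `durations_s`,
#'   `alternations_per_min`, `n_switches`, and (if `fit`) a tibble `fits`
#'   with `dist`, `par1`, `par2`, `mean_nll`, plus `reliable`.
#' @export
duration_stats <- function(periods, total_minutes = NULL, fit = TRUE) {
  durations_s <- periods$duration_ms / 1000
  sides <- periods$side
  n_switch <- if (length(sides) >= 2) sum(sides[-1] != sides[-length(sides)]) else 0L
  alt <- if (!is.null(total_minutes)) n_switch / total_minutes else NA_real_
  out <- list(durations_s = durations_s, n_switches = n_switch,
              alternations_per_min = alt)
  if (fit && length(durations_s) >= 2) {
    fit_one <- function(dist) {
      f <- fitdistrplus::fitdist(durations_s, dist)
      tibble::tibble(dist = dist,
                     par1 = unname(f$estimate[1]),
                     par2 = unname(f$estimate[2]),
                     mean_nll = -stats::logLik(f)[1] / length(durations_s))
    }
    out$fits <- dplyr::bind_rows(fit_one("gamma"), fit_one("lnorm"),
                                 fit_one("norm"))
    # gamma rate -> scale for reporting
    out$gamma_shape <- out$fits$par1[out$fits$dist == "gamma"]
    out$gamma_scale <- 1 / out$fits$par2[out$fits$dist == "gamma"]
    out$reliable <- length(durations_s) >= 20
  }
  structure(out, class = "dominance_stats")
}

#' @export
glance.dominance_stats <- function(x, ...) {
  tibble::tibble(
    n_periods = length(x$durations_s),
    mean_duration_s = mean(x$durations_s),
    alternations_per_min = x$alternations_per_min,
    gamma_shape = x$gamma_shape %||% NA_real_,
    gamma_scale = x$gamma_scale %||% NA_real_
  )
}

#' Optimal spike-count criterion for detection
#'
#' Scans every integer criterion between the smallest and largest observed
#' count; a present trial is a miss when its count is `<=` the criterion
#' and an absent trial a false alarm when its count exceeds it. Returns the
#' smallest criterion minimising misses + false alarms pooled across all
#' stimulus intensities.
#'
#' @param counts Tibble with `intensity` (0 = stimulus absent) and
#'   `count` (spikes in the response window).
#' @return Integer criterion.
#' @export
optimal_criterion <- function(counts) {
  stopifnot(any(counts$intensity == 0))
  absent <- counts$count[counts$intensity == 0]
  present <- counts$count[counts$intensity > 0]
  if (length(absent) == 0 || nrow(counts) == 0) stop("empty condition")
  crits <- seq(min(counts$count), max(counts$count))
  errs <- vapply(crits, function(cr) {
    sum(present <= cr) + sum(absent > cr)
  }, numeric(1))
  crits[which.min(errs)]
}

#' Response probabilities under a criterion
#'
#' @param counts Tibble with `intensity`, `count`.
#' @param criterion Spike-count criterion (response iff `count > criterion`).
#' @return Tibble with `intensity`, `n`, `p_response`.
#' @export
response_probability <- function(counts, criterion) {
  counts |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(n = dplyr::n(),
                     p_response = mean(.data$count > criterion),
                     .groups = "drop")
}

#' Fit a four-parameter psychometric function
#'
#' Bounded nonlinear least squares fit of
#' `P(x) = gamma + (1 - gamma - lambda) / (1 + exp(-beta (x - alpha)))`:
#' threshold `alpha`, slope `beta`, lapse rate `lambda`, guess rate
#' `gamma` (both rates bounded to `[0, 1]`, `alpha` to the intensity
#' range).
#'
#' @param data Tibble with `intensity` and `p_response`.
#' @param start Optional named start values.
#' @return Object of class `psychfit` with `par`, `fitted`, `residuals`,
#'   `data`, `converged`.
#' @export
fit_psychometric <- function(data, start = NULL) {
  stopifnot(length(unique(data$intensity)) >= 4)
  x <- data$intensity; y <- data$p_response
  start <- start %||% list(alpha = stats::median(x),
                           beta = 4 / max(diff(range(x)), 1),
                           lambda = 0.02, gamma = max(min(y), 0.01))
  fit <- try(minpack.lm::nlsLM(
    y ~ gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha))),
    start = start,
    lower = c(alpha = min(x), beta = -Inf, lambda = 0, gamma = 0),
    upper = c(alpha = max(x), beta = Inf, lambda = 1, gamma = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(par = NULL, converged = FALSE, data = data,
                          residuals = y), class = "psychfit"))
  }
  structure(list(par = as.list(stats::coef(fit)),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 data = data, converged = TRUE),
            class = "psychfit")
}

#' Evaluate the psychometric function
#'
#' @param x Intensity.
#' @param alpha,beta,lambda,gamma Parameters (threshold, slope, lapse,
#'   guess).
#' @return Response probability.
#' @export
psychometric_fun <- function(x, alpha, beta, lambda = 0, gamma = 0) {
  gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))
}

#' @export
tidy.psychfit <- function(x, ...) {
  if (!x$converged) return(tibble::tibble(term = character(), estimate = numeric()))
  tibble::tibble(term = names(x$par), estimate = unlist(x$par))
}

#' @export
glance.psychfit <- function(x, ...) {
  tibble::tibble(converged = x$converged,
                 rss = sum(x$residuals^2),
                 threshold = x$par$alpha %||% NA_real_,
                 slope = x$par$beta %||% NA_real_)
}

#' @export
print.psychfit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<psychfit> alpha=%.2f beta=%.4f lambda=%.3f gamma=%.3f\n",
                x$par$alpha, x$par$beta, x$par$lambda, x$par$gamma))
  else cat("<psychfit> not converged\n")
  invisible(x)
}

#' Tie-aware ROC area under the curve
#'
#' AUC of present-vs-absent spike counts, computed as the normalised
#' Mann-Whitney U statistic (rank formulation with average ranks, so ties
#' contribute 1/2).
#'
#' @param present,absent Integer count vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(present, absent) {
  n1 <- length(present); n0 <- length(absent)
  if (n1 == 0 || n0 == 0) stop("empty condition")
  r <- rank(c(present, absent))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Neurometric function
#'
#' Per-intensity ROC AUC of present-vs-absent counts, normalised across
#' conditions so the curve spans `[0, 1]`: `(AUC - min AUC) / (max AUC -
#' min AUC)` with the extrema taken over all intensities of the condition
#' set.
#'
#' @param counts Tibble with `intensity` (0 = absent) and `count`.
#' @return Tibble with `intensity`, `auc`, `p_response`.
#' @export
neurometric <- function(counts) {
  absent <- counts$count[counts$intensity == 0]
  if (length(absent) == 0) stop("stimulus-absent condition required")
  res <- counts |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(auc = roc_auc(.data$count, absent), .groups = "drop")
  rng <- range(res$auc)
  res$p_response <- if (diff(rng) > 0) (res$auc - rng[1]) / diff(rng)
                    else rep(0, nrow(res))
  res
}

#' Side-resolved regime summaries and switch-triggered averages
#'
#' From a traced recording: per-side time series of burst fraction
#' (somas in the IB regime), above-B1 fraction (apical input current above
#' the first bifurcation), mean coupling and mean distance-to-B1; their
#' means over the supplied dominance periods (dominant side only); and
#' switch-triggered averages in a fixed window around each detected
#' switch.
#'
#' @param recording A traced `tc_recording`.
#' @param left_cells,right_cells Cell masks of the two competing
#'   populations.
#' @param periods Dominance tibble from [detect_dominance()].
#' @param I_B1 First bifurcation current (pA).
#' @param switch_window_ms Half-width of the switch-triggered window.
#' @return A list with `timeseries` (tibble: `time_ms`, `side`,
#'   `burst_fraction`, `above_b1_fraction`, `mean_coupling`,
#'   `mean_distance_pa`), `dominant_means` (one-row tibble averaged over
#'   dominance periods, dominant side), and `switch_triggered` (tibble:
#'   `lag_ms` plus the same four variables for the newly dominant side).
#' @export
regime_summaries <- function(recording, left_cells, right_cells, periods,
                             I_B1 = bifurcation_points()$I_B1,
                             switch_window_ms = 1000) {
  tr <- recording$traces
  if (is.null(tr)) stop("recording has no traces (record_traces = FALSE)")
  t_ms <- tr$time_ms

  side_ts <- function(cells, side) {
    tibble::tibble(
      time_ms = t_ms, side = side,
      burst_fraction = rowMeans(tr$regime[, cells, drop = FALSE]),
      above_b1_fraction = rowMeans(tr$apical_input[, cells, drop = FALSE] > I_B1),
      mean_coupling = rowMeans(tr$coupling[, cells, drop = FALSE]),
      mean_distance_pa = rowMeans(tr$apical_input[, cells, drop = FALSE]) - I_B1
    )
  }
  ts <- dplyr::bind_rows(side_ts(left_cells, "left"),
                         side_ts(right_cells, "right"))

  dom_rows <- purrr::pmap_dfr(periods, function(side, start_ms, end_ms, ...) {
    sel <- ts$side == side & ts$time_ms >= start_ms & ts$time_ms <= end_ms
    dplyr::summarise(ts[sel, ],
                     burst_fraction = mean(.data$burst_fraction),
                     above_b1_fraction = mean(.data$above_b1_fraction),
                     mean_coupling = mean(.data$mean_coupling),
                     mean_distance_pa = mean(.data$mean_distance_pa),
                     n_steps = sum(sel))
  })
  dominant_means <- if (nrow(dom_rows) > 0) {
    w <- dom_rows$n_steps / sum(dom_rows$n_steps)
    tibble::tibble(
      burst_fraction = sum(dom_rows$burst_fraction * w),
      above_b1_fraction = sum(dom_rows$above_b1_fraction * w),
      mean_coupling = sum(dom_rows$mean_coupling * w),
      mean_distance_pa = sum(dom_rows$mean_distance_pa * w)
    )
  } else {
    tibble::tibble(burst_fraction = NA_real_, above_b1_fraction = NA_real_,
                   mean_coupling = NA_real_, mean_distance_pa = NA_real_)
  }

  # switch-triggered averages: align on starts of dominance periods that
  # follow a period of the other side
  sw <- NULL
  if (nrow(periods) >= 2) {
    switches <- periods$start_ms[-1][periods$side[-1] != periods$side[-nrow(periods)]]
    new_side <- periods$side[-1][periods$side[-1] != periods$side[-nrow(periods)]]
    if (length(switches) > 0) {
      dt_tr <- if (length(t_ms) > 1) diff(t_ms)[1] else 1
      lags <- seq(-switch_window_ms, switch_window_ms, by = dt_tr)
      acc <- purrr::map2(switches, new_side, function(s0, sd) {
        sel_t <- s0 + lags
        idx <- round((sel_t - t_ms[1]) / dt_tr) + 1L
        ok <- idx >= 1 & idx <= length(t_ms)
        sub <- ts[ts$side == sd, ]
        m <- matrix(NA_real_, length(lags), 4)
        m[ok, ] <- as.matrix(sub[idx[ok], c("burst_fraction", "above_b1_fraction",
                                            "mean_coupling", "mean_distance_pa")])
        m
      })
      avg <- Reduce(`+`, purrr::map(acc, function(m) ifelse(is.na(m), 0, m))) /
        Reduce(`+`, purrr::map(acc, function(m) !is.na(m) * 1))
      sw <- tibble::tibble(lag_ms = lags,
                           burst_fraction = avg[, 1],
                           above_b1_fraction = avg[, 2],
                           mean_coupling = avg[, 3],
                           mean_distance_pa = avg[, 4])
    }
  }

  list(timeseries = ts, dominant_means = dominant_means,
       switch_triggered = sw)
}
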