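# The experiment protocols are exercised at reduced size (few seeds, a
# coarse intensity grid); the full-size statistics live in the acceptance
# checks.

test_that("threshold detection shows a sigmoid and the perturbation signature", {
  res <- run_threshold_detection(intensities = c(0, 100, 200, 350),
                                 seeds = 1:6)
  resp <- tidyr::pivot_wider(res$response, names_from = "arm",
                             values_from = "p_response")
  # control: response probability non-decreasing with intensity, spanning
  # chance to near-certainty
  expect_true(all(diff(resp$control) >= -0.1))
  expect_lte(resp$control[resp$intensity == 0], 0.6)
  expect_equal(resp$control[resp$intensity == 350], 1, tolerance = 0.2)
  # inhibitions never respond more than control beyond binomial noise;
  # excitation's shift is asserted on the evoked activity below
  expect_gte(mean(resp$apical_exc - resp$control), -0.15)
  expect_lte(mean(resp$apical_inh - resp$control), 0.05)
  expect_lte(mean(resp$thalamus_inh - resp$control), 0.05)
  # mechanism: apical inhibition acts through distance-to-bifurcation,
  # thalamic inhibition through the coupling probability
  mech <- res$mechanism
  ctrl <- mech[mech$arm == "control", ]
  ainh <- mech[mech$arm == "apical_inh", ]
  tinh <- mech[mech$arm == "thalamus_inh", ]
  aexc <- mech[mech$arm == "apical_exc", ]
  expect_lt(ainh$mean_distance_pa, ctrl$mean_distance_pa)
  expect_gt(aexc$mean_distance_pa, ctrl$mean_distance_pa)
  expect_lt(tinh$mean_coupling, ctrl$mean_coupling)
  expect_lt(abs(tinh$mean_distance_pa - ctrl$mean_distance_pa),
            abs(ainh$mean_distance_pa - ctrl$mean_distance_pa))
  expect_lt(ainh$burst_fraction, ctrl$burst_fraction)
  expect_lt(tinh$burst_fraction, ctrl$burst_fraction)
  # neurometric curves exist per arm and span [0, 1]
  expect_true(all(res$neurometric$p_response >= 0 &
                    res$neurometric$p_response <= 1))
  # zero intensity responds at the false-alarm rate by definition
  fa <- res$counts[res$counts$arm == "control" & res$counts$intensity == 0, ]
  expect_equal(resp$control[resp$intensity == 0],
               mean(fa$count > res$criterion))
})

test_that("rivalry produces exclusive alternating dominance", {
  res <- run_rivalry_batch(c(1400, 1400), seeds = 3:5)
  expect_true(all(res$n_periods > 0))
  pooled <- dplyr::bind_rows(res$periods)
  # both sides take dominance
  expect_setequal(unique(pooled$side), c("left", "right"))
  # periods never overlap within a run
  for (p in res$periods) {
    p <- p[order(p$start_ms), ]
    if (nrow(p) > 1) expect_true(all(diff(p$start_ms) >=
                                       p$duration_ms[-nrow(p)] - 1))
  }
  # dominant-state summaries are populated and bounded
  expect_true(all(res$burst_fraction >= 0 & res$burst_fraction <= 1))
  expect_true(all(res$mean_coupling >= 0 & res$mean_coupling <= 1))
})

test_that("asymmetric perturbations shift the perturbed side's durations", {
  res <- run_rivalry_perturbation("asym", seeds = 3:5,
    arms = list(apical_exc_400 = perturbation_spec("apical", "left", 400),
                apical_inh_400 = perturbation_spec("apical", "left", -400)))
  byarm <- res |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(durL = mean(.data$mean_duration_left_s, na.rm = TRUE),
                     durR = mean(.data$mean_duration_right_s, na.rm = TRUE))
  ctrl <- byarm[byarm$arm == "control", ]
  exc <- byarm[byarm$arm == "apical_exc_400", ]
  inh <- byarm[byarm$arm == "apical_inh_400", ]
  expect_gt(exc$durL, ctrl$durL)   # excited side lengthens
  expect_lt(inh$durL, ctrl$durL)   # inhibited side shortens
  # unperturbed side comparatively unchanged under excitation
  expect_lt(abs(exc$durR - ctrl$durR) / ctrl$durR, 0.8)
})

test_that("the noise-free probe runs deterministically and reports alternation", {
  res <- run_limit_cycle_probe(duration = 8000, kick_time = 3000, seed = 2)
  expect_setequal(res$probe, c("asym_no_kick", "sym_kick", "asym_kick"))
  expect_true(all(vapply(res$periods, is.data.frame, logical(1))))
  expect_type(res$alternating_after_kick, "logical")
})

test_that("fixtures are reproducible and carry their stated structure", {
  d1 <- make_fixtures("durations", n = 500, seed = 3)
  d2 <- make_fixtures("durations", n = 500, seed = 3)
  expect_identical(d1, d2)
  expect_length(d1, 500)
  expect_true(all(d1 > 0))
  det <- make_fixtures("detection", n = 100, seed = 4)
  expect_true(all(det$p_response >= 0 & det$p_response <= 1))
  expect_named(attr(det, "true_par"), c("alpha", "beta", "lambda", "gamma"))
})
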