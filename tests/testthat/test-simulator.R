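short_cfg <- function(...) {
  tc_config(duration = 1500, seed = 14, burn_in = 500, ...)
}

test_that("runs are bit-identical for identical config and seed", {
  r1 <- run_simulation(short_cfg())
  r2 <- run_simulation(short_cfg())
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$traces$apical_input, r2$traces$apical_input)
  expect_identical(r1$traces$coupling, r2$traces$coupling)
  # a different seed gives a different raster
  r3 <- run_simulation(short_cfg(), seed = 15)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("zero drive leaves the network silent at rest", {
  cfg <- short_cfg(drive = drive_spec(background_soma_rate = 0,
                                      background_apical_rate = 0))
  r <- run_simulation(cfg)
  expect_equal(nrow(r$spikes), 0)
  expect_true(all(r$traces$coupling == 0))
  expect_true(all(r$traces$regime == 0))
})

test_that("state variables respect their hard bounds over a full run", {
  r <- run_simulation(tc_config(duration = 5000, seed = 3))
  expect_true(all(r$traces$coupling >= 0 & r$traces$coupling <= 1))
  expect_true(all(r$traces$regime %in% c(0L, 1L)))
  expect_true(all(r$spikes$time_ms >= 0 &
                    r$spikes$time_ms <= r$config$duration))
  expect_true(all(r$spikes$cell >= 1))
})

test_that("noise-free mode is deterministic in its drive and kick timing works", {
  cfg <- tc_config(duration = 1200, seed = 5, burn_in = 0, noise_free = TRUE,
                   drive = drive_spec(stim_kind = "rivalry",
                                      rivalry_rates = c(1400, 1400)),
                   kick = list(amplitude = 200, onset = 600, duration = 50,
                               side = "left"),
                   record_traces = FALSE)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("spike counts are dt-robust for a driven single-cell network", {
  # halving dt changes the total spike count only slightly at fixed rate
  cfg1 <- tc_config(duration = 2000, seed = 8, dt = 0.1, burn_in = 0,
                    record_traces = FALSE)
  cfg2 <- tc_config(duration = 2000, seed = 8, dt = 0.05, burn_in = 0,
                    record_traces = FALSE)
  n1 <- nrow(run_simulation(cfg1)$spikes)
  n2 <- nrow(run_simulation(cfg2)$spikes)
  expect_gt(n1, 0)
  # different dt implies different noise realisations; compare rates loosely
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.30)
})

test_that("batch runs are independent and aggregate like their parts", {
  cfg <- short_cfg(record_traces = FALSE)
  recs <- run_batch(cfg, seeds = c(21, 22))
  expect_length(recs, 2)
  expect_false(identical(recs[[1]]$spikes, recs[[2]]$spikes))
  counts <- purrr::map_dbl(recs, ~ nrow(.x$spikes))
  mapped <- run_batch(cfg, seeds = c(21, 22), map_fn = function(r) nrow(r$spikes))
  expect_equal(unlist(mapped), counts)
})

test_that("recordings round-trip through CSV + JSON losslessly", {
  r <- run_simulation(short_cfg(record_traces = FALSE))
  tmp <- tempfile(fileext = ".csv")
  write_recording(r, tmp)
  back <- read_recording(tmp)
  expect_equal(as.data.frame(back$spikes), as.data.frame(r$spikes))
  expect_equal(back$meta$seed, r$seed)
  expect_equal(back$meta$duration, r$config$duration)
  unlink(c(tmp, paste0(tmp, ".meta.json")))
})
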