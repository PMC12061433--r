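test_that("ISI CV is zero for regular trains and matches a direct oracle for bursts", {
  reg <- tibble::tibble(population = "exc", cell = 1L,
                        time_ms = seq(0, 1000, by = 100))
  expect_equal(isi_cv(reg), 0)
  # bursty train: pairs 5 ms apart separated by 500 ms
  t_b <- as.vector(rbind(seq(0, 5000, by = 500), seq(5, 5005, by = 500)))
  isis <- diff(sort(t_b))
  oracle <- sd(isis) / mean(isis)
  burst <- tibble::tibble(population = "exc", cell = 1L, time_ms = t_b)
  expect_equal(isi_cv(burst), oracle)
  expect_error(isi_cv(reg, population = "thal"), "no spikes")
})

test_that("population rate conserves spike count and averages over the mask", {
  none <- tibble::tibble(population = "exc", cell = 1L, time_ms = numeric(0))
  r0 <- population_rate(none, cells = 1:45, t_max = 1000)
  expect_true(all(r0$rate_hz == 0))
  # one cell at 10 Hz in a 45-cell mask -> ~10/45 Hz steady state
  sp <- tibble::tibble(population = "exc", cell = 7L,
                       time_ms = seq(50, 9950, by = 100))
  r <- population_rate(sp, cells = 1:45, t_max = 10000)
  expect_equal(mean(r$rate_hz[200:10000]), 10 / 45, tolerance = 0.01)
  # conservation: mean rate * n_cells * duration = total spikes
  expect_equal(mean(r$rate_hz) * 45 * 10, nrow(sp), tolerance = 0.02)
  expect_error(population_rate(sp, cells = integer(0), t_max = 100), "empty")
})

test_that("dominance detector applies the strict 5 Hz / 250 ms rule", {
  t_ms <- 1:1000
  mk <- function(l, r) detect_dominance(l, r, t_ms)
  # left 10 Hz vs 0 Hz for 300 ms
  l <- rep(0, 1000); l[101:400] <- 10
  p <- mk(l, rep(0, 1000))
  expect_equal(nrow(p), 1)
  expect_equal(p$side, "left")
  expect_equal(p$duration_ms, 300)
  # difference exactly 5 Hz is NOT dominance
  expect_equal(nrow(mk(rep(5, 1000), rep(0, 1000))), 0)
  # 6 Hz for only 200 ms fails the minimum-duration filter
  l2 <- rep(0, 1000); l2[101:300] <- 6
  expect_equal(nrow(mk(l2, rep(0, 1000))), 0)
  # side swap symmetry
  p_swap <- mk(rep(0, 1000), l)
  expect_equal(p_swap$side, "right")
  expect_equal(p_swap$duration_ms, p$duration_ms)
})

test_that("constructed rate fixture yields exactly its three dominance periods", {
  fx <- make_fixtures("rates")
  p <- detect_dominance(fx$left, fx$right)
  expect_equal(nrow(p), 3)
  expect_equal(p$side, fx$true_periods$side)
  expect_equal(p$duration_ms, fx$true_periods$duration_ms)
})

test_that("duration statistics count alternations and recover Gamma parameters", {
  # alternating L,R,L,R over one minute -> 3 switches
  per <- tibble::tibble(side = c("left", "right", "left", "right"),
                        start_ms = c(0, 15, 30, 45) * 1000,
                        end_ms = c(14, 29, 44, 59) * 1000,
                        duration_ms = rep(14000, 4))
  st <- duration_stats(per, total_minutes = 1, fit = FALSE)
  expect_equal(st$n_switches, 3)
  expect_equal(st$alternations_per_min, 3)
  # Gamma MLE recovery at n = 1e4 within 5%
  set.seed(5)
  d <- stats::rgamma(1e4, shape = 4.85, scale = 0.56)
  per2 <- tibble::tibble(side = "left", start_ms = 0, end_ms = 0,
                         duration_ms = d * 1000)
  st2 <- duration_stats(per2, total_minutes = NULL)
  expect_equal(st2$gamma_shape, 4.85, tolerance = 0.05 * 4.85)
  expect_equal(st2$gamma_scale, 0.56, tolerance = 0.05 * 0.56)
  expect_true(st2$reliable)
})

test_that("model comparison prefers Gamma on right-skewed durations", {
  set.seed(6)
  d <- stats::rgamma(2000, shape = 4.85, scale = 0.56)
  per <- tibble::tibble(side = "left", start_ms = 0, end_ms = 0,
                        duration_ms = d * 1000)
  st <- duration_stats(per)
  nll <- setNames(st$fits$mean_nll, st$fits$dist)
  expect_lt(nll[["gamma"]], nll[["norm"]])
  expect_lt(nll[["gamma"]], nll[["lnorm"]])
  # grid-search likelihood oracle for the gamma fit
  grid <- expand.grid(shape = seq(4, 6, by = 0.02),
                      scale = seq(0.4, 0.8, by = 0.005))
  gnll <- mapply(function(sh, sc) -mean(stats::dgamma(d, sh, scale = sc, log = TRUE)),
                 grid$shape, grid$scale)
  best <- grid[which.min(gnll), ]
  expect_equal(st$gamma_shape, best$shape, tolerance = 0.03)
  expect_lte(nll[["gamma"]], min(gnll) + 1e-6)
})

test_that("optimal criterion minimises misses plus false alarms with smallest tie-break", {
  counts <- tibble::tibble(intensity = rep(c(0, 100), each = 3),
                           count = c(1, 2, 3, 5, 6, 7))
  expect_equal(optimal_criterion(counts), 3)
  # degenerate: all counts identical
  flat <- tibble::tibble(intensity = rep(c(0, 100), each = 3), count = rep(4, 6))
  expect_equal(optimal_criterion(flat), 4)
  # exhaustive-scan oracle on random data
  set.seed(8)
  rnd <- tibble::tibble(intensity = rep(c(0, 50, 100), each = 20),
                        count = rpois(60, lambda = rep(c(5, 7, 12), each = 20)))
  cr <- optimal_criterion(rnd)
  errs <- vapply(min(rnd$count):max(rnd$count), function(k) {
    sum(rnd$count[rnd$intensity > 0] <= k) + sum(rnd$count[rnd$intensity == 0] > k)
  }, numeric(1))
  ks <- (min(rnd$count):max(rnd$count))
  expect_equal(cr, ks[which.min(errs)])
  # overlap floor: identical distributions cannot beat ~half errors
  same <- tibble::tibble(intensity = rep(c(0, 100), each = 50),
                         count = rep(rpois(50, 10), 2))
  best_err <- min(vapply(min(same$count):max(same$count), function(k) {
    sum(same$count[same$intensity > 0] <= k) + sum(same$count[same$intensity == 0] > k)
  }, numeric(1)))
  expect_gte(best_err, 50 * 0.9)
})

test_that("psychometric function has its asymptotes and recovers parameters", {
  expect_equal(psychometric_fun(150, 150, 0.05), 0.5)
  expect_equal(psychometric_fun(1e9, 150, 0.05, lambda = 0.07, gamma = 0.1),
               0.93, tolerance = 1e-6)
  expect_equal(psychometric_fun(-1e9, 150, 0.05, lambda = 0.07, gamma = 0.1),
               0.1, tolerance = 1e-6)
  # recovery oracle: binomial data from known parameters, 30 trials/level
  set.seed(12)
  true <- list(alpha = 150, beta = 0.05, lambda = 0.05, gamma = 0.1)
  boot_ok <- 0
  est <- replicate(40, {
    x <- seq(0, 350, by = 50)
    pr <- psychometric_fun(x, true$alpha, true$beta, true$lambda, true$gamma)
    y <- rbinom(length(x), 30, pr) / 30
    f <- fit_psychometric(tibble::tibble(intensity = x, p_response = y))
    if (f$converged) c(f$par$alpha, f$par$beta) else c(NA, NA)
  })
  expect_equal(median(est[1, ], na.rm = TRUE), true$alpha, tolerance = 0.15 * 150)
  expect_equal(median(est[2, ], na.rm = TRUE), true$beta, tolerance = 0.5 * 0.05)
  # tidy/glance methods expose the fit
  x <- seq(0, 350, by = 50)
  f <- fit_psychometric(tibble::tibble(
    intensity = x,
    p_response = psychometric_fun(x, 150, 0.05, 0.05, 0.1)))
  expect_true(f$converged)
  td <- tidy(f)
  expect_setequal(td$term, c("alpha", "beta", "lambda", "gamma"))
  expect_equal(unname(td$estimate[td$term == "alpha"]), 150, tolerance = 1)
  expect_true(glance(f)$converged)
})

test_that("ROC AUC equals the tie-corrected Mann-Whitney statistic", {
  expect_equal(roc_auc(c(2, 3, 3, 4), c(0, 1, 1, 2)),
               {
                 w <- wilcox.test(c(2, 3, 3, 4), c(0, 1, 1, 2), exact = FALSE)
                 unname(w$statistic) / 16
               })
  # identical distributions -> 0.5; disjoint -> 1
  set.seed(3)
  x <- rpois(200, 8)
  expect_equal(roc_auc(x, x), 0.5)
  expect_equal(roc_auc(101:150, 1:50), 1)
  # random integer counts vs wilcox oracle
  for (i in 1:10) {
    a <- rpois(30, 10); b <- rpois(25, 8)
    expect_equal(roc_auc(a, b),
                 unname(wilcox.test(a, b, exact = FALSE)$statistic) / (30 * 25))
  }
})

test_that("neurometric normalisation spans [0, 1] across conditions", {
  set.seed(9)
  counts <- tibble::tibble(
    intensity = rep(c(0, 50, 100, 200), each = 30),
    count = rpois(120, rep(c(5, 6, 9, 15), each = 30)))
  nm <- neurometric(counts)
  expect_equal(min(nm$p_response), 0)
  expect_equal(max(nm$p_response), 1)
  expect_true(all(nm$auc >= 0 & nm$auc <= 1))
  expect_error(neurometric(counts[counts$intensity > 0, ]), "absent")
})

test_that("detection fixture reproduces its generating curve", {
  fx <- make_fixtures("detection", n = 5000, seed = 2)
  tp <- attr(fx, "true_par")
  expect_equal(fx$p_response, fx$true_p, tolerance = 0.05)
  f <- fit_psychometric(fx[, c("intensity", "p_response")])
  expect_true(f$converged)
  expect_equal(f$par$alpha, tp$alpha, tolerance = 15)
})
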