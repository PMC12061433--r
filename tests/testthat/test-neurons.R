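test_that("apical nonlinearity and resting fixed point behave as derived", {
  p <- apical_params()
  # half-activation at -38 mV, slope 6 mV
  expect_equal(apical_f(-38), 0.5)
  expect_equal(apical_f(-32), 1 / (1 + exp(-1)))
  # v-nullcline root at u = I = 0: -l (v - v_r) + g f(v) = 0, solved
  # numerically (independent of the engine)
  root <- uniroot(function(v) -p$l * (v - p$v_r) + p$g * apical_f(v),
                  c(-70, -60), tol = 1e-10)$root
  drift <- -p$l * (root - p$v_r) + p$g * apical_f(root)
  expect_lt(abs(drift), 1e-6)
})

test_that("soma quadratic term vanishes at rest and resets use the active regime", {
  cells <- default_cell_params()
  soma <- cells$soma
  # dv/dt at v = v_r, u = 0, I = 0 is exactly 0
  dv <- soma$k * (soma$v_r - soma$v_r) * (soma$v_r - soma$v_t)
  expect_identical(dv, 0)
  # RS and IB reset pairs as tabulated: IB reset nearer threshold, weaker
  # spike adaptation
  expect_equal(soma$regimes$RS$c, -65)
  expect_equal(soma$regimes$RS$d, 250)
  expect_equal(soma$regimes$IB$c, -55)
  expect_equal(soma$regimes$IB$d, 150)
  expect_lt(soma$regimes$RS$c, soma$regimes$IB$c)
  expect_lt(soma$regimes$IB$d, soma$regimes$RS$d)
})

test_that("coupling variable saturates at 1 and decays exponentially", {
  syn <- default_synapse_params()
  # one spike from 0 jumps to 1 (saturating jump)
  g <- 0
  g <- g + (1 - g) * 1
  expect_equal(g, 1)
  # exact exponential decay over 800 ms
  expect_equal(1 * exp(-800 / syn$tau_coupling), exp(-1))
  # two spikes in one step: sequential jump map is idempotent at 1
  g <- 0.5
  for (k in 1:2) g <- g + (1 - g)
  expect_equal(g, 1)
})

test_that("single soma firing under constant drive matches a fine-step reference", {
  # forward-Euler integration of one Izhikevich soma at dt = 0.1 vs
  # dt = 0.001 ms (oracle: same equations, 100x finer step)
  sim_soma <- function(dt, I = 600, t_max = 1000) {
    p <- default_cell_params()$soma
    v <- p$v_r; u <- 0; n <- 0
    steps <- round(t_max / dt)
    for (k in seq_len(steps)) {
      vn <- v + dt * (p$k * (v - p$v_r) * (v - p$v_t) - u + I) / p$C
      u <- u + dt * p$a * (p$b * (v - p$v_r) - u)
      if (vn >= p$v_peak) {
        n <- n + 1
        vn <- p$regimes$RS$c
        u <- u + p$regimes$RS$d
      }
      v <- vn
    }
    n
  }
  expect_lte(abs(sim_soma(0.1) - sim_soma(0.001)), 1)
})

test_that("bAP scheduling is Bernoulli in the coupling probability", {
  set.seed(11)
  draws <- runif(1e5) < 0.3
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  # degenerate probabilities
  expect_true(all(runif(100) < 1))
  expect_false(any(runif(100) < 0))
})

test_that("adaptation conductance follows its decay and increment rules", {
  s <- step_adaptation(0, spiked = 1, dt = 0.1)
  expect_equal(s, 0.065, tolerance = 1e-6)
  expect_equal(step_adaptation(0.065, 0, dt = 2000), 0.065 / exp(1))
  expect_equal(adaptation_current(5, -80), 0)
  expect_equal(adaptation_current(2, -60), -40)
})
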