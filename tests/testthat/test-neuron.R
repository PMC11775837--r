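test_that("membrane decay follows the exponential leak", {
  n <- neuron_state(tau_m = 18)
  n <- decay_potential(n, 5000)
  expect_equal(n$V, 0)

  n <- neuron_state(tau_m = 18)
  n$V <- 10
  n <- decay_potential(n, 18000)   # dt = tau_m
  expect_equal(n$V, 10 * exp(-1), tolerance = 1e-12)

  expect_error(decay_potential(n, 0), "backwards")
})

test_that("decay is time-consistent for every exponential term", {
  set.seed(1)
  for (rep in 1:20) {
    n <- neuron_state(tau_m = 18, tau_SRA = 100, tau_RP = 20)
    n$V <- runif(1, -20, 30)
    n$V_SRA <- runif(1, 0, 3)
    n$t_s <- 0
    dt1 <- runif(1, 1, 5e4); dt2 <- runif(1, 1, 5e4)
    a <- decay_potential(decay_potential(n, dt1), dt1 + dt2)
    b <- decay_potential(n, dt1 + dt2)
    expect_equal(a$V, b$V, tolerance = 1e-12)
    expect_equal(a$V_SRA, b$V_SRA, tolerance = 1e-12)
    expect_equal(saec:::refractory_term(a, dt1 + dt2),
                 saec:::refractory_term(b, dt1 + dt2), tolerance = 1e-12)
  }
})

test_that("synaptic delivery adds or subtracts with the inhibition floor", {
  n <- neuron_state()
  n <- deliver_spike(n, 5, 0, "excitatory")
  expect_equal(n$V, 5)
  n$V <- 10
  n <- deliver_spike(n, 40, 0, "inhibitory")
  expect_equal(n$V, -30)            # floored at V_min
  n <- deliver_spike(n, 0, 0, "excitatory")
  expect_equal(n$V, -30)
  expect_error(deliver_spike(n, -1, 0, "excitatory"), "non-negative")
})

test_that("threshold crossing spikes, resets and arms the homeostatic traces", {
  n <- neuron_state(V_thresh = 30, V_reset = -20)
  n$V <- 31
  n$last_update <- 1000
  res <- fire_if_threshold(n, 1000)
  expect_true(res$spiked)
  expect_equal(res$state$V, -20)
  expect_equal(res$state$t_s, 1000)
  expect_equal(res$state$V_SRA, 0.6)
  expect_lt(saec:::effective_potential(res$state, 1000),
            res$state$V_theta)      # post-reset invariant

  n <- neuron_state(V_thresh = 30)
  n$V <- 29.99
  expect_false(fire_if_threshold(n, 0)$spiked)
})

test_that("the refractory trace suppresses immediate re-firing", {
  n <- neuron_state(V_thresh = 5, V_reset = 0, eta_RP = 1, tau_RP = 20,
                    eta_SRA = 0)
  n$V <- 6
  res <- fire_if_threshold(n, 0)
  expect_true(res$spiked)
  n <- res$state
  # 1 us later, drive the membrane to just above threshold: the armed
  # refractory term (~ -1 mV) must hold the cell back
  n <- deliver_spike(n, 5.5, 1, "excitatory")
  expect_false(fire_if_threshold(n, 1)$spiked)
  # with a bit more drive it fires despite the trace
  n <- deliver_spike(n, 1, 1, "excitatory")
  expect_true(fire_if_threshold(n, 1)$spiked)
})

test_that("static inhibition subtracts eta_I with the floor", {
  tg <- neuron_state(); tg$V <- 10
  out <- apply_static_inhibition(list(tg), eta_I = 15)
  expect_equal(out[[1]]$V, -5)
  tg$V <- -30
  out <- apply_static_inhibition(list(tg), eta_I = 15)
  expect_equal(out[[1]]$V, -30)
  tg$V <- 10
  out <- apply_static_inhibition(list(tg), eta_I = 0)
  expect_equal(out[[1]]$V, 10)
})

test_that("threshold adaptation moves with the rate error and clamps", {
  n <- neuron_state(V_thresh = 30)
  n$S <- 0.75
  expect_equal(update_threshold(n, 1, 0.75)$V_theta, 30)
  n$S <- 1.5
  expect_equal(update_threshold(n, 1, 0.75)$V_theta, 31)
  n$S <- 0
  for (k in 1:100) n <- update_threshold(n, 1, 0.75, floor = 1)
  expect_equal(n$V_theta, 1)
})

test_that("kernel rate estimation is normalized and unbiased for Poisson input", {
  expect_equal(estimate_rate(numeric(), 0), 0)
  expect_equal(estimate_rate(1000, 1000), 0)  # kappa(0) = 0
  expect_error(estimate_rate(c(5, 1), 10), "ordered")

  # closed form: integral of the kernel is exactly 1
  tk <- 0.1; nk <- 0.005
  integral <- integrate(function(t) (exp(-t / tk) - exp(-t / nk)) / (tk - nk),
                        0, Inf)$value
  expect_equal(integral, 1, tolerance = 1e-8)

  set.seed(21)
  dur <- 20
  spikes <- sort(runif(rpois(1, 50 * dur), 0, dur)) * 1e6
  ts <- seq(5, dur, by = 0.05) * 1e6
  est <- vapply(ts, function(t)
    estimate_rate(spikes[spikes <= t], t), numeric(1))
  expect_lt(abs(mean(est) / 50 - 1), 0.1)
})
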