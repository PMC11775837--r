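test_that("population value decoding is affine in the mean rate", {
  expect_equal(critic_value(rep(0, 100)), -20)
  expect_equal(critic_value(rep(0.02, 100), nu = 1000, V0 = -20, E_norm = 1),
               0)
  # doubling rates and the normalizer leaves the value unchanged
  r <- runif(50, 0, 0.05)
  expect_equal(critic_value(r, E_norm = 2), critic_value(2 * r, E_norm = 4))
})

test_that("the numerical value derivative averages central differences", {
  expect_equal(as.numeric(value_derivative(rep(3, 50))), 0)
  v <- seq(0, 49) * 0.3          # slope 0.3 per ms
  expect_equal(as.numeric(value_derivative(v, N = 10, eta_actor = 80)),
               80 * 0.3, tolerance = 1e-10)
  expect_equal(as.numeric(value_derivative(v, N = 1, eta_actor = 80)),
               80 * 0.3, tolerance = 1e-10)
  short <- value_derivative(c(1, 2), N = 10)
  expect_equal(as.numeric(short), 0)
  expect_true(attr(short, "short"))
})

test_that("the continuous TD error has the stated fixed point and signs", {
  expect_equal(td_error(0, 7, 7 / 1, tau_r = 1), 0)   # self-consistency
  expect_equal(td_error(0, 0, 5), 5)                  # underestimated
  expect_lt(td_error(0, 3, 0), 0)                     # overestimated
})

test_that("eligibility traces decay exponentially and match brute force", {
  tr <- accumulate_eligibility(NULL, 1, t_now = 0)
  tr <- accumulate_eligibility(tr, 0, t_now = 250000)  # dt = tau_e
  expect_equal(tr$value, exp(-1), tolerance = 1e-12)

  tr <- accumulate_eligibility(NULL, 0, 0)
  tr <- accumulate_eligibility(tr, 0, 1e6)
  expect_equal(tr$value, 0)

  # incremental accumulation equals recomputation from the full log
  set.seed(13)
  times <- sort(runif(100, 0, 5e5))
  incs <- runif(100, -0.1, 0.3)
  tr <- NULL
  for (i in seq_along(times))
    tr <- accumulate_eligibility(tr, incs[i], times[i])
  t_end <- times[length(times)]
  brute <- sum(incs * exp(-(t_end - times) / (250 * 1000)))
  expect_equal(tr$value, brute, tolerance = 1e-9)
})

test_that("three-factor updates multiply trace and TD error, gated per group", {
  expect_equal(apply_three_factor(0, 0.5, delta = 0.2, eta = 0.2), 0.02)
  w <- runif(10)
  expect_equal(apply_three_factor(w, runif(10), delta = 0, eta = 0.2), w)
  gate <- rep(c(TRUE, FALSE), 5)
  w2 <- apply_three_factor(w, rep(1, 10), delta = 1, eta = 0.1, gate = gate)
  expect_equal(w2[!gate], w[!gate])
  expect_equal(w2[gate], w[gate] + 0.1)
  # clamped at zero
  expect_equal(apply_three_factor(0.01, 1, delta = -1, eta = 1), 0)
})

test_that("action selection is winner-take-all with exploration", {
  set.seed(2)
  expect_equal(as.integer(select_action(c(10, 3), lambda_EXP = 0)), 1L)

  draws <- replicate(4000, as.integer(select_action(c(1, 5), lambda_EXP = 1)))
  p <- mean(draws == 1)
  expect_gt(p, 0.5 - 3 * sqrt(0.25 / 4000))
  expect_lt(p, 0.5 + 3 * sqrt(0.25 / 4000))

  ties <- replicate(4000, as.integer(select_action(c(5, 5), lambda_EXP = 0)))
  p <- mean(ties == 1)
  expect_gt(p, 0.5 - 3 * sqrt(0.25 / 4000))
  expect_lt(p, 0.5 + 3 * sqrt(0.25 / 4000))
})

test_that("the schedule decays geometrically with the action-interval floor", {
  s <- aec_schedule()
  s1 <- decay_schedule(s)
  expect_equal(s1$eta_critic, 0.2 * 0.95)
  expect_equal(s1$eta_actor, 0.1 * (1 - 1.66 / 100))
  for (k in 1:200) s <- decay_schedule(s)
  expect_equal(s$action_interval, 10)      # clamped at the floor
  expect_equal(s$lambda_EXP, 0.75 * 0.95^200, tolerance = 1e-9)
})
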