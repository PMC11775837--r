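test_that("exponential STDP matches its closed form at the window landmarks", {
  # coincident pre/post spike: the full LTP height (simple-cell value)
  expect_equal(stdp_exponential(10000, 10000, -Inf), 0.00077)
  # one LTP time constant in the past
  expect_equal(stdp_exponential(10000 - 7000, 10000, -Inf),
               0.00077 * exp(-1), tolerance = 1e-12)
  # pre-spike older than the previous post-spike contributes nothing
  expect_equal(stdp_exponential(1000, 10000, 5000), 0)
  # inside the window: LTP minus LTD per the two exponentials
  got <- stdp_exponential(8000, 10000, 6000)
  want <- 0.00077 * exp((8000 - 10000) / 7000) -
    0.00021 * exp((6000 - 8000) / 14000)
  expect_equal(got, want, tolerance = 1e-15)
  # contributions sum over the source's in-window spikes
  expect_equal(stdp_exponential(c(8000, 9000), 10000, 6000),
               stdp_exponential(8000, 10000, 6000) +
                 stdp_exponential(9000, 10000, 6000), tolerance = 1e-15)
})

test_that("step STDP uses inclusive bounds and is always potentiating", {
  # exactly on the LTP boundary (complex-cell window, 20 ms)
  expect_equal(stdp_step(30000 - 20000, 30000, -1e9), 0.2)
  # just outside both windows
  expect_equal(stdp_step(30000 - 20001, 30000, -1e9), 0)
  # inside both windows: both positive parts add
  expect_equal(stdp_step(25000, 30000, 24000), 0.4)
  expect_gte(stdp_step(sort(runif(20, 0, 5e4)), 30000, 10000), 0)
})

test_that("L1 normalization rescales, clamps and is idempotent", {
  expect_equal(normalize_weights(c(3, 4), 4), c(12 / 7, 16 / 7))
  w <- normalize_weights(runif(10), 4)
  expect_equal(sum(w), 4)
  expect_equal(normalize_weights(w, 4), w, tolerance = 1e-12)
  expect_equal(normalize_weights(numeric(3), 4), numeric(3))
  expect_equal(sum(normalize_weights(c(-1, 2, 3), 4)), 4)
  expect_true(all(normalize_weights(c(-1, 2, 3), 4) >= 0))
})
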