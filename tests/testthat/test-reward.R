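test_that("activity tracking is the stated exponential moving average", {
  tr <- activity_tracker(alpha = 0.75)
  tr <- update_activity(tr, spikes_in_bin = 4, events_in_bin = 8)
  expect_equal(tr$S, 3)      # 0.75 * 4 + 0.25 * 0
  expect_equal(tr$E, 6)

  for (k in 1:50) tr <- update_activity(tr, 5, 5)
  expect_equal(tr$S, 5, tolerance = 1e-6)   # fixed point at constant input

  tr2 <- activity_tracker(); tr2$S <- 8
  tr2 <- update_activity(tr2, 0, 0)
  expect_equal(tr2$S, 8 * 0.25)             # geometric decay ratio (1-alpha)

  expect_error(update_activity(tr, -1, 0), "negative")
})

test_that("the intrinsic reward is high for efficient encoding", {
  tr <- activity_tracker()
  tr$S <- 90; tr$E <- 20
  expect_equal(as.numeric(compute_reward(tr)), 0)   # offset cancellation
  tr$S <- 80; tr$E <- 10
  expect_equal(as.numeric(compute_reward(tr)), 5)   # 5 * (90 - 80) / 10

  # strictly decreasing in activity at fixed event rate
  r <- vapply(seq(0, 120, by = 10), function(s) {
    tr$S <- s; as.numeric(compute_reward(tr))
  }, numeric(1))
  expect_true(all(diff(r) < 0))

  # silent input: reward held at zero and flagged
  tr$S <- 10; tr$E <- 0.5
  out <- compute_reward(tr, epsilon = 1)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "starved"))
})
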