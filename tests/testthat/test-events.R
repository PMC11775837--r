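test_that("event streams validate coordinates and stay time-ordered", {
  s <- event_stream(t = c(10, 5, 5), x = c(1, 2, 0), y = c(0, 1, 1),
                    polarity = c(1, 0, 1), width = 4, height = 2)
  expect_equal(s$t, c(5, 5, 10))
  expect_equal(s$x, c(0L, 2L, 1L))      # ties broken by y, then x
  expect_error(event_stream(1, 4, 0, 1, width = 4, height = 2),
               "geometry")
  expect_error(event_stream(1, 0, 0, 2, width = 4, height = 2),
               "polarity")
  expect_error(event_stream(-1, 0, 0, 1, width = 4, height = 2),
               "negative")
})

test_that("event CSV round trip is lossless and rejects bad rows", {
  set.seed(42)
  s <- event_stream(t = sort(sample.int(1e6, 50)),
                    x = sample(0:7, 50, TRUE), y = sample(0:3, 50, TRUE),
                    polarity = sample(0:1, 50, TRUE),
                    width = 8, height = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(s, f)
  expect_stream_equal(read_events(f), s)

  empty <- event_stream(width = 8, height = 4)
  write_events(empty, f)
  r <- read_events(f)
  expect_equal(nrow(r), 0)
  expect_identical(attr(r, "width"), 8L)

  # row with x == width must be rejected with its row index
  writeLines(c("# 4,2", "t_us,x,y,polarity", "10,4,0,1"), f)
  expect_error(read_events(f), "row 1")
})

test_that("frame-to-event conversion counts log-threshold crossings", {
  th <- 0.25
  f1 <- matrix(1, 4, 4)
  # two identical frames: no events
  expect_equal(nrow(frames_to_events(list(f1, f1), th)), 0)

  # one pixel steps up by 1.05 thresholds in log-intensity: exactly 1 ON
  f2 <- f1
  f2[2, 3] <- (1 + 0.05) * exp(1.05 * th) - 0.05
  s <- frames_to_events(list(f1, f2), th, I_floor = 0.05)
  expect_equal(nrow(s), 1)
  expect_equal(s$polarity, 1L)
  expect_equal(c(s$x, s$y), c(2L, 1L))  # 0-based

  # a step down by 2.5 thresholds: floor(2.5) = 2 OFF events in the interval
  f3 <- f1
  f3[1, 1] <- (1 + 0.05) * exp(-2.5 * th) - 0.05
  s <- frames_to_events(list(f1, f3), th, I_floor = 0.05)
  expect_equal(nrow(s), 2)
  expect_equal(s$polarity, c(0L, 0L))
  expect_true(all(s$t > 0 & s$t < 1000))  # spread inside the interval

  expect_error(frames_to_events(list(f1, matrix(1, 3, 3)), th), "geometry")
  expect_error(event_converter(4, 4, threshold = 0), "positive")
})

test_that("event count from a drifting edge is linear in drift distance", {
  th <- 0.25
  count_for <- function(shift_px) {
    frames <- lapply(0:shift_px, function(k) {
      f <- matrix(0.1, 6, 30)
      f[, seq_len(5) + k] <- 1
      f
    })
    nrow(frames_to_events(frames, th))
  }
  counts <- vapply(c(2, 4, 8), count_for, numeric(1))
  # brute-force crossing counts: each pixel toggling emits the same number
  # of events, so counts scale with the distance moved
  expect_equal(counts[2] / counts[1], 2, tolerance = 0.05)
  expect_equal(counts[3] / counts[1], 4, tolerance = 0.05)
})

test_that("time jitter preserves the event multiset up to timestamps", {
  set.seed(7)
  s <- event_stream(t = sort(sample.int(5e5, 1000)),
                    x = sample(0:9, 1000, TRUE), y = sample(0:9, 1000, TRUE),
                    polarity = sample(0:1, 1000, TRUE),
                    width = 10, height = 10)
  expect_stream_equal(jitter_event_times(s, 0), s)
  j <- jitter_event_times(s, 1000)
  expect_equal(nrow(j), nrow(s))
  key <- function(d) sort(paste(d$x, d$y, d$polarity))
  expect_equal(key(j), key(s))
  expect_true(all(j$t >= 0))
  # E|U(-500, 500)| = 250 us
  s0 <- event_stream(t = rep(1e6, 1000), x = rep(0, 1000), y = rep(0, 1000),
                     polarity = rep(1, 1000), width = 2, height = 2)
  j0 <- jitter_event_times(s0, 1000)
  expect_lt(abs(mean(abs(j0$t - 1e6)) / 250 - 1), 0.1)
})

test_that("Ornstein-Uhlenbeck jitter relaxes to mu and matches the stationary variance", {
  s <- ou_state(position = 5, theta = 4, mu = 0, sigma = 0)
  for (k in 1:100) {
    prev <- s$position
    s <- ou_step(s, 0.01)
    expect_lt(abs(s$position), abs(prev) + 1e-12)
  }
  expect_lt(abs(s$position), 0.2)

  s <- ou_state(position = 3, theta = 4, mu = 3, sigma = 0)
  s <- ou_step(s, 0.01)
  expect_equal(s$position, 3)

  set.seed(11)
  s <- ou_state(0, theta = 4, mu = 0, sigma = 1)
  xs <- numeric(40000)
  for (k in seq_along(xs)) {
    s <- ou_step(s, 0.001)
    xs[k] <- s$position
  }
  xs <- xs[-(1:2000)]
  expect_lt(abs(mean(xs)), 0.05)
  expect_lt(abs(var(xs) / (1 / (2 * 4)) - 1), 0.1)

  set.seed(3); a <- ou_step(ou_state(c(0, 0)), 0.001)
  set.seed(3); b <- ou_step(ou_state(c(0, 0)), 0.001)
  expect_identical(a$position, b$position)
  expect_error(ou_state(theta = 0), "theta")
})
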