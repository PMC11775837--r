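test_that("rendering is deterministic and centers the stimulus at zero error", {
  cfg <- aec_config("tracking", "desk")
  e <- aec_env(cfg)
  e$ou$sigma <- 0
  f1 <- render_tick(e); f2 <- render_tick(e)
  expect_identical(f1, f2)
  # ball (bright pixels) centered horizontally
  ball <- which(f1 >= 0.4, arr.ind = TRUE)   # ball pixels (stripes incl.)
  expect_equal(mean(ball[, 2]), (ncol(f1) + 1) / 2, tolerance = 0.05)

  cfg2 <- aec_config("stabilization", "desk")
  e2 <- aec_env(cfg2)
  e2$ou$sigma <- 0
  f <- render_tick(e2)
  # at zero orientation the bars are horizontal: within the aperture, rows
  # are uniform while columns alternate
  mid <- f[20:44, 28:36]                      # inside the aperture
  expect_true(all(apply(mid, 1, function(r) length(unique(r)) == 1)))
  expect_gt(length(unique(f[20:44, 32])), 1)
})

test_that("the C++ closed-loop renderer matches the R renderer", {
  for (task in c("tracking", "stabilization")) {
    cfg <- aec_config(task, "desk")
    e <- aec_env(cfg)
    e$ou$sigma <- 0
    for (err in c(-0.4, 0, 0.3)) {
      e$error <- err * e$fov_half
      sp <- saec:::env_speeds(e)
      envp <- list(task = task, width = e$width, height = e$height,
                   fov_half = e$fov_half, error = e$error, gaze = e$gaze,
                   drift_dir = 1,
                   ou_theta = cfg$env$ou_theta, ou_sigma = cfg$env$ou_sigma,
                   cam_speed = sp$cam, drift_speed = sp$drift,
                   ball_r = if (task == "tracking")
                     cfg$env$ball_radius_frac * e$height else 0,
                   n_stripes = if (task == "tracking")
                     cfg$env$n_stripes else 0,
                   n_bars = if (task == "tracking") 0 else cfg$env$n_bars,
                   duty = if (task == "tracking") 0 else cfg$env$bar_duty,
                   threshold = cfg$converter$threshold,
                   I_floor = cfg$converter$I_floor)
      fr_cpp <- saec:::eng_render_frame(envp, 0, 0)
      fr_r <- render_tick(e)
      expect_equal(fr_cpp, fr_r, tolerance = 1e-12)
    }
  }
})

test_that("environment dynamics: correct action reduces the error; wrapping", {
  cfg <- aec_config("tracking", "desk")
  e <- aec_env(cfg)
  e$ou$sigma <- 0
  env_reset(e, value = 0.5)
  e$drift_dir <- 0                    # isolate the action
  env_step(e, action = 2, dt_ms = 0)  # turn right, toward the ball
  for (k in 1:100) {
    prev <- e$error
    env_step(e, dt_ms = 1, drift = FALSE)
    expect_lt(abs(e$error), abs(prev) + 1e-12)
  }
  # opposite actions are symmetric about the drift-free trajectory
  e1 <- aec_env(cfg); e1$ou$sigma <- 0; env_reset(e1, value = 0)
  e2 <- aec_env(cfg); e2$ou$sigma <- 0; env_reset(e2, value = 0)
  env_step(e1, 1, dt_ms = 0); env_step(e2, 2, dt_ms = 0)
  for (k in 1:50) {
    env_step(e1, dt_ms = 1, drift = FALSE)
    env_step(e2, dt_ms = 1, drift = FALSE)
  }
  expect_equal(e1$error, -e2$error, tolerance = 1e-12)

  # wrap-around into (-pi, pi]
  e$error <- pi - 0.001
  e$action_vel <- -1000 * (2 * e$fov_half)   # large leftward step
  env_step(e, dt_ms = 1, drift = FALSE)
  expect_true(e$error > -pi && e$error <= pi)

  expect_error(env_step(e, action = 7), "unknown action")

  es <- aec_env(aec_config("stabilization", "desk"))
  es$error <- pi / 2 - 0.001
  es$action_vel <- -1000
  env_step(es, dt_ms = 1, drift = FALSE)
  expect_true(es$error > -pi / 2 && es$error <= pi / 2)
})

test_that("reset distributions behave as specified", {
  cfg <- aec_config("tracking", "desk")
  e <- aec_env(cfg)
  set.seed(14)
  draws <- replicate(10000, { env_reset(e, "centered-normal"); e$error })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)

  b <- replicate(6, { env_reset(e, "border"); e$error })
  expect_true(all(abs(b) > 0.5 * e$fov_half))
  expect_true(all(diff(sign(b)) != 0))   # alternating sides

  set.seed(5); env_reset(e, "uniform"); a1 <- e$error
  set.seed(5); env_reset(e, "uniform"); a2 <- e$error
  expect_identical(a1, a2)
})

test_that("a moving ball produces far more events than a stationary one", {
  cfg <- aec_config("tracking", "desk")
  count_events <- function(moving) {
    e <- aec_env(cfg)
    e$ou$sigma <- 0                 # isolate stimulus motion
    env_reset(e, value = 0)
    e$drift_dir <- if (moving) 1 else 0
    conv <- event_converter(e$width, e$height, cfg$converter$threshold,
                            cfg$converter$I_floor)
    n <- 0
    for (k in 1:300) {
      env_step(e, action = 0, dt_ms = 1, drift = moving)
      n <- n + nrow(convert_step(conv, render_tick(e), k * 1000))
    }
    n
  }
  expect_gt(count_events(TRUE), 10 * max(count_events(FALSE), 1))
})

test_that("validation sweeps cover the range and conserve spike counts", {
  set.seed(20)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  env <- aec_env(cfg)
  sw <- validation_sweep(net, env, n_bins = 10, pass_ms = 300, passes = 1)
  expect_true(all(sw$visits >= 1))              # every bin visited
  st <- saec:::eng_status(net$ptr)
  expect_equal(sum(sw$events), st$events)       # conservation
  expect_equal(sum(sw$simple), st$simple)
  cts <- saec:::eng_cell_counts(net$ptr, reset = FALSE)
  nc <- cfg$rl$n_critic
  expect_equal(sum(sw$critic), sum(cts$rl[seq_len(nc)]))
})
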