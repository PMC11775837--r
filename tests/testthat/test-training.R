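test_that("each training stage freezes exactly the stated weight groups", {
  set.seed(12)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  invisible(run_stage(net, "train-coding",
                      stream = synth_stream("moving-bar", cfg, 1200),
                      repeats = 10))
  w1 <- coef(net)

  # inhibition training leaves every excitatory tensor bit-identical
  invisible(run_stage(net, "train-inhibition",
                      stream = synth_stream("center-osc", cfg, 500,
                                            time_jitter = FALSE),
                      repeats = 20))
  w2 <- coef(net)
  expect_identical(w2$simple_maps, w1$simple_maps)
  expect_identical(w2$complex, w1$complex)
  expect_false(identical(w2$lateral, w1$lateral))

  # agent training leaves the whole encoder untouched
  invisible(run_stage(net, "train-agent", duration_s = 4))
  w3 <- coef(net)
  expect_identical(w3$simple_maps, w2$simple_maps)
  expect_identical(w3$complex, w2$complex)
  expect_identical(w3$lateral, w2$lateral)
  expect_identical(w3$topdown, w2$topdown)

  # validation changes no weights at all
  invisible(run_stage(net, "validate", duration_s = 2))
  expect_identical(coef(net), w3)
})

test_that("early agent training explores at the configured rate", {
  set.seed(30)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  # before any schedule decay, about 75% of actions are random
  tr <- run_stage(net, "train-agent", duration_s = 1.8)
  m <- tr$metrics
  expect_gt(nrow(m), 4)
  p <- mean(m$explored)
  n_all <- 0
  # pool several short runs for a stable binomial check
  for (k in 1:6) {
    tr <- run_stage(net, "train-agent", duration_s = 1.8)
    m <- rbind(m, tr$metrics)
  }
  p <- mean(m$explored)
  se <- sqrt(0.75 * 0.25 / nrow(m))
  expect_lt(abs(p - 0.75), 4 * se + 0.02)
})

test_that("stage results carry metrics, traces and reproducible pipelines", {
  run_pipe <- function() {
    set.seed(44)
    cfg <- aec_config("tracking", "desk")
    net <- aec_network(cfg)
    tr <- run_stage(net, "train-agent", duration_s = 3)
    va <- run_stage(net, "validate", duration_s = 2)
    list(m = tr$metrics, t = va$trace)
  }
  a <- run_pipe(); b <- run_pipe()
  expect_identical(a$m, b$m)       # full pipeline reproducibility
  expect_identical(a$t, b$t)
  expect_true(all(c("t_ms", "action", "V", "delta", "R") %in% names(a$m)))
  expect_equal(nrow(a$t), 2000)
  expect_true(any(a$t$reset))
})

test_that("return-rate scoring counts post-reset recoveries", {
  trace <- data.frame(
    t_ms = 1:3000,
    error = c(rep(1, 1000), seq(1, 0, length.out = 500), rep(0.01, 1500)),
    reset = FALSE)
  trace$reset[c(1000, 2500)] <- TRUE
  out <- return_rate(trace, tol = 0.1, within_ms = 1000)
  expect_equal(out$n_resets, 2)
  expect_equal(out$n_returned, 2)
  trace$error[2501:3000] <- 2       # second reset never recovers
  out <- return_rate(trace, tol = 0.1, within_ms = 600)
  expect_equal(out$n_returned, 1)
})

test_that("the critic recovers programmed state values on the two-state toy", {
  set.seed(17)
  ex <- critic_recovery_experiment(train_s = 30, probe_s = 2)
  # a short run only needs to order the values correctly
  expect_gt(ex$V_A, ex$V_B)
  expect_equal(attr(ex, "class"), NULL)
  expect_true(is.finite(ex$mean_delta_late))
})
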