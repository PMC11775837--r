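test_that("network objects print, summarize and expose coefficients", {
  set.seed(1)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  expect_s3_class(net, "aec_network")
  expect_output(print(net), "aec_network")
  expect_output(print(summary(net)), "events")
  w <- coef(net)
  expect_named(w, c("simple_maps", "complex", "lateral", "topdown",
                    "critic", "actor"))
  expect_length(w$simple_maps, cfg$geometry$s_maps)
  expect_equal(dim(w$critic),
               c(cfg$rl$n_critic,
                 cfg$geometry$n_simple + cfg$geometry$n_complex))
})

test_that("predict() encodes a stream without touching any weights", {
  set.seed(2)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  invisible(run_stage(net, "train-coding",
                      stream = synth_stream("moving-bar", cfg, 1000)))
  w_before <- coef(net)
  p <- predict(net, synth_stream("moving-bar", cfg, 500))
  expect_identical(coef(net), w_before)
  expect_equal(sum(p$per_cell_simple), p$simple_spikes)
  expect_gt(p$events, 0)
  expect_equal(sum(p$bins$events), p$events)
})

test_that("stream replay and tick-by-tick feeding drive the engine identically", {
  set.seed(9)
  cfg <- aec_config("tracking", "desk")
  s <- synth_stream("moving-bar", cfg, 400)
  set.seed(33); n1 <- aec_network(cfg)
  invisible(saec:::feed_stream(n1, s))
  set.seed(33); n2 <- aec_network(cfg)
  invisible(saec:::replay_stream(n2, s, repeats = 1))
  expect_identical(saec:::eng_get_state(n1$ptr), saec:::eng_get_state(n2$ptr))
})

test_that("synthetic streams respect geometry and are reproducible", {
  cfg <- aec_config("stabilization", "desk")
  for (kind in c("moving-bar", "grating", "center-osc")) {
    set.seed(4)
    s <- synth_stream(kind, cfg, 150)
    expect_gt(nrow(s), 0)
    expect_true(all(s$x >= 0 & s$x < attr(s, "width")))
    expect_true(all(s$y >= 0 & s$y < attr(s, "height")))
    expect_true(!is.unsorted(s$t))
    set.seed(4)
    expect_stream_equal(synth_stream(kind, cfg, 150), s)
  }
})
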