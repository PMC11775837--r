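test_that("event-driven engine matches the clocked pure-R oracle", {
  set.seed(31)
  cfg <- tiny_config(maps = 10, V_thresh = 3)
  net <- aec_network(cfg)
  w0 <- coef(net)$simple_maps          # engine's random initial weights
  ev <- tiny_events(1000, dur_ms = 500)

  feed_tiny(net, ev)
  w_eng <- coef(net)$simple_maps
  # lazy engine potentials live at each cell's last update; bring them to
  # the final tick for comparison with the clocked oracle
  st <- saec:::eng_get_state(net$ptr)
  end_ms <- ceiling(max(ev$t))
  V_eng <- st$simple$V * exp(-(end_ms - st$simple$last_up) / cfg$simple$tau_m)

  oracle <- r_oracle_simple(cfg, w0, ev)
  for (i in seq_len(10)) {
    expect_equal(w_eng[[i]], unname(oracle$weights[[i]]), tolerance = 1e-9)
    expect_equal(V_eng[i], oracle$cells[[i]]$V, tolerance = 1e-9)
  }
  # spike counts agree exactly
  counts <- saec:::eng_cell_counts(net$ptr, reset = FALSE)$simple
  or_counts <- tabulate(oracle$spikes[, 1], nbins = 10)
  expect_equal(counts, or_counts)
  expect_gt(sum(counts), 0)            # the instance actually spiked
})

test_that("longer lazy-update runs stay within 1e-9 mV of the oracle", {
  set.seed(77)
  cfg <- tiny_config(maps = 10)
  net <- aec_network(cfg)
  w0 <- coef(net)$simple_maps
  ev <- tiny_events(800, dur_ms = 1900)  # sparse drive over ~2 s
  feed_tiny(net, ev)
  oracle <- r_oracle_simple(cfg, w0, ev)
  st <- saec:::eng_get_state(net$ptr)
  end_ms <- ceiling(max(ev$t))
  V_eng <- st$simple$V * exp(-(end_ms - st$simple$last_up) / cfg$simple$tau_m)
  for (i in seq_len(10))
    expect_equal(V_eng[i], oracle$cells[[i]]$V, tolerance = 1e-9)
})

test_that("excitatory weight norms equal lambda after plasticity", {
  set.seed(5)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  invisible(run_stage(net, "train-coding",
                      stream = synth_stream("moving-bar", cfg, 1500)))
  w <- coef(net)
  for (m in w$simple_maps)
    expect_equal(sum(m), cfg$simple$lambda, tolerance = 1e-9)
  for (cwv in w$complex)
    expect_equal(sum(cwv), cfg$complex$lambda, tolerance = 1e-9)
  # inhibitory stores are bounded by their caps
  expect_true(all(vapply(w$lateral, sum, numeric(1)) <=
                    cfg$simple$lambda_lateral + 1e-9))
  expect_true(all(vapply(w$topdown, sum, numeric(1)) <=
                    cfg$simple$lambda_topdown + 1e-9))
  expect_true(all(unlist(w$simple_maps) >= 0))
  expect_true(all(unlist(w$lateral) >= 0))
})

test_that("an event fans out to every map at the covered location", {
  set.seed(8)
  cfg <- tiny_config(maps = 16)
  net <- aec_network(cfg)
  V0 <- saec:::eng_membrane(net$ptr, "simple")
  saec:::eng_feed_events(net$ptr, 0.5, 1L, 1L, 1L)
  V1 <- saec:::eng_membrane(net$ptr, "simple")
  expect_equal(sum(V1 != V0), 16)      # all maps' membranes moved
  expect_error(saec:::eng_feed_events(net$ptr, 1, 99L, 0L, 1L), "retina")
})

test_that("identical seeds give bit-identical runs; checkpoints resume exactly", {
  run_once <- function() {
    set.seed(99)
    cfg <- aec_config("tracking", "desk")
    net <- aec_network(cfg)
    r <- run_stage(net, "train-coding",
                   stream = synth_stream("moving-bar", cfg, 800))
    list(bins = r$bins, w = coef(net), st = saec:::eng_status(net$ptr))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$bins, b$bins)
  expect_identical(a$w, b$w)

  # checkpoint round trip: resumed trajectory == uninterrupted trajectory
  set.seed(123)
  cfg <- aec_config("tracking", "desk")
  net <- aec_network(cfg)
  s1 <- synth_stream("moving-bar", cfg, 600)
  s2 <- synth_stream("moving-bar", cfg, 600)
  invisible(run_stage(net, "train-coding", stream = s1))
  snap <- aec_state(net)
  invisible(run_stage(net, "train-coding", stream = s2))
  w_direct <- coef(net)

  net2 <- aec_restore(snap)
  invisible(run_stage(net2, "train-coding", stream = s2))
  expect_identical(coef(net2), w_direct)
  expect_identical(saec:::eng_get_state(net2$ptr),
                   saec:::eng_get_state(net$ptr))
})

test_that("engine eligibility traces equal brute-force recomputation", {
  set.seed(55)
  cfg <- tiny_config(maps = 4)
  net <- aec_network(cfg)
  # wire one critic neuron to fire exactly at source-0 spikes
  st <- saec:::eng_get_state(net$ptr)
  st$critic_w <- lapply(st$critic_w, function(w) { w[] <- 0; w })
  st$critic_w[[1]][1] <- 50           # fires on every source-0 spike
  saec:::eng_set_state(net$ptr, st)
  saec:::eng_set_flags(net$ptr, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)

  all_times <- sample(seq(50, 2000, by = 0.5), 100)
  post_times <- sort(all_times[1:40])              # ms, source 0 drives
  other_times <- sort(all_times[41:100])           # ms, source 1 only logs
  all_ev <- rbind(data.frame(t = post_times, src = 0L),
                  data.frame(t = other_times, src = 1L))
  all_ev <- all_ev[order(all_ev$t), ]
  for (i in seq_len(nrow(all_ev)))
    saec:::eng_inject_spikes(net$ptr, all_ev$src[i], all_ev$t[i])
  t_end <- max(all_ev$t)
  elig <- saec:::eng_eligibility(net$ptr, t_end)

  # brute force: at each post spike, the STDP sum over source-1 spikes in
  # [previous post, post], accumulated with exp(-dt/tau_e) decay
  p <- cfg$critic
  trace <- 0; prev <- -Inf; last_t <- NULL
  for (k in seq_along(post_times)) {
    ts <- post_times[k]
    inc <- stdp_exponential(other_times[other_times <= ts] * 1000,
                            ts * 1000,
                            if (is.finite(prev)) prev * 1000 else -Inf,
                            p$eta_LTP, p$eta_LTD, p$tau_LTP, p$tau_LTD)
    if (!is.null(last_t)) trace <- trace * exp(-(ts - last_t) / p$tau_e)
    trace <- trace + inc
    last_t <- ts
    prev <- ts
  }
  trace <- trace * exp(-(t_end - last_t) / p$tau_e)
  expect_equal(elig$critic[1, 2], trace, tolerance = 1e-9)
})
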