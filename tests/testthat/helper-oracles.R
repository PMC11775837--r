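# Independent reference implementations used as oracles for the C++ engine.
# These are deliberately written from the pure R operation functions, not
# from the engine's code path.

# a minimal configuration: one receptive-field location, `maps` cells,
# complex layer silenced, all plastic inhibition and homeostatic threshold
# adaptation off unless asked for
tiny_config <- function(maps = 10, rfw = 4, rfh = 4, V_thresh = 30, ...) {
  g <- list(width = rfw, height = rfh,
            s_gw = 1, s_gh = 1, s_maps = maps, s_rfw = rfw, s_rfh = rfh,
            c_gw = 1, c_gh = 1, c_maps = 1, c_rfw = 1, c_rfh = 1)
  g$s_stride_x <- rfw; g$s_stride_y <- rfh
  g$c_stride_x <- 1; g$c_stride_y <- 1
  g$n_simple <- maps; g$n_complex <- 1
  aec_config("tracking", "desk", geometry = g,
             simple = list(eta_TA = 0, V_thresh = V_thresh),
             complex = list(V_thresh = 1e9), ...)
}

# clocked pure-R simulator of the simple-cell layer for one location:
# excitatory STDP with weight sharing degenerates to per-cell weights here,
# plus static cross-map inhibition. Potentials are decayed at every 1 ms
# boundary *and* at event times, exercising decay consistency.
r_oracle_simple <- function(cfg, weights, events_ms) {
  p <- cfg$simple
  maps <- cfg$geometry$s_maps
  rfw <- cfg$geometry$s_rfw; rfh <- cfg$geometry$s_rfh
  n_src <- rfw * rfh * 2
  cells <- lapply(seq_len(maps), function(i)
    neuron_state(V_thresh = p$V_thresh, V_reset = p$V_reset,
                 tau_m = p$tau_m, tau_SRA = p$tau_SRA,
                 eta_SRA = p$eta_SRA, tau_RP = p$tau_RP, eta_RP = p$eta_RP,
                 V_min = cfg$V_min))
  pix_log <- vector("list", n_src)
  spikes <- list()
  n_events <- nrow(events_ms)
  end_ms <- ceiling(max(events_ms$t))
  ev_i <- 1
  for (tick in seq_len(end_ms)) {
    while (ev_i <= n_events && events_ms$t[ev_i] <= tick) {
      ev <- events_ms[ev_i, ]
      t_us <- ev$t * 1000
      src <- (ev$polarity * rfh + ev$y) * rfw + ev$x + 1
      pix_log[[src]] <- c(pix_log[[src]], ev$t)
      for (i in seq_len(maps)) {
        cells[[i]] <- deliver_spike(cells[[i]], weights[[i]][src], t_us,
                                    "excitatory")
        res <- fire_if_threshold(cells[[i]], t_us)
        if (res$spiked) {
          cells[[i]] <- res$state
          spikes[[length(spikes) + 1]] <- c(i, ev$t)
          # shared-map STDP (one location: the map's own pre log)
          ts <- ev$t; tsm1 <- cells[[i]]$t_sm1 / 1000
          dw <- vapply(pix_log, function(lg)
            stdp_exponential(if (is.null(lg)) numeric() else lg * 1000,
                             ts * 1000,
                             if (is.finite(tsm1)) tsm1 * 1000 else -Inf,
                             p$eta_LTP, p$eta_LTD, p$tau_LTP, p$tau_LTD),
            numeric(1))
          weights[[i]] <- normalize_weights(weights[[i]] + dw, p$lambda)
          # static inhibition of the other maps
          for (j in seq_len(maps)[-i]) {
            cells[[j]] <- decay_potential(cells[[j]], t_us)
            cells[[j]]$V <- max(cfg$V_min, cells[[j]]$V - p$eta_I)
          }
        } else {
          cells[[i]] <- res$state
        }
      }
      ev_i <- ev_i + 1
    }
    for (i in seq_len(maps))
      cells[[i]] <- decay_potential(cells[[i]], tick * 1000)
  }
  list(cells = cells, weights = weights,
       spikes = if (length(spikes)) do.call(rbind, spikes) else NULL)
}

# random event batch on a tiny retina (times in ms, strictly ordered)
tiny_events <- function(n, rfw = 4, rfh = 4, dur_ms = 500) {
  t <- sort(round(stats::runif(n, 1, dur_ms), 3))
  data.frame(t = t,
             x = sample.int(rfw, n, replace = TRUE) - 1L,
             y = sample.int(rfh, n, replace = TRUE) - 1L,
             polarity = sample(0:1, n, replace = TRUE))
}

# feed a tiny event data frame (ms) into an engine-backed network
feed_tiny <- function(net, events_ms) {
  end_ms <- ceiling(max(events_ms$t))
  ev_i <- 1
  n <- nrow(events_ms)
  for (tick in seq_len(end_ms)) {
    idx <- which(events_ms$t > tick - 1 & events_ms$t <= tick)
    if (length(idx))
      saec:::eng_feed_events(net$ptr, events_ms$t[idx], events_ms$x[idx],
                             events_ms$y[idx], events_ms$polarity[idx])
    saec:::eng_tick(net$ptr, tick)
  }
  net$t_ms <- end_ms
  invisible(net)
}

expect_stream_equal <- function(a, b) {
  expect_equal(a$t, b$t)
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$polarity, b$polarity)
  expect_identical(attr(a, "width"), attr(b, "width"))
  expect_identical(attr(a, "height"), attr(b, "height"))
}
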