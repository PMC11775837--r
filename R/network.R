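#' Create a spiking active-efficient-coding network
#'
#' Instantiates the full model: the two-layer spiking encoder (simple cells
#' with shared receptive-field weights; complex pooling cells; static,
#' lateral and top-down inhibition) and the spiking actor-critic populations,
#' with weights initialized uniformly at random and normalized. Uses R's RNG:
#' call `set.seed()` first for reproducible initialization.
#'
#' The returned object is stateful (it owns the simulation engine); training
#' functions such as [run_stage()] advance it in place and also return it
#' invisibly.
#'
#' @param config an [aec_config()].
#' @return an object of class `aec_network`.
#' @examples
#' set.seed(1)
#' net <- aec_network(aec_config("tracking", scale = "desk"))
#' net
#' @export
aec_network <- function(config = aec_config()) {
  stopifnot(inherits(config, "aec_config"))
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$ptr <- aec_engine_new(unclass(config))
  net$t_ms <- 0
  net$schedule <- aec_schedule(
    lambda_EXP = config$rl$lambda_EXP,
    action_interval = config$rl$action_interval,
    action_interval_min = config$rl$action_interval_min,
    eta_critic = config$critic$eta, eta_actor = config$actor$eta,
    eta_decay_critic = config$critic$eta_decay,
    eta_decay_actor = config$actor$eta_decay,
    Delta_decay = config$rl$Delta_decay)
  net$stages <- character()
  class(net) <- "aec_network"
  net
}

#' Extract or restore the complete network state
#'
#' `aec_state()` captures every weight tensor, neuron state, spike-history
#' buffer, tracker and schedule variable (plus the R RNG state) as a plain R
#' list; `aec_restore()` rebuilds a network from it. A restored network
#' continues bit-exactly: resuming from a checkpoint reproduces the
#' uninterrupted trajectory. The list can be persisted with `saveRDS()`.
#'
#' @param net an [aec_network()].
#' @return `aec_state`: a list; `aec_restore`: an `aec_network`.
#' @export
aec_state <- function(net) {
  stopifnot(inherits(net, "aec_network"))
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  list(config = net$config, engine = eng_get_state(net$ptr),
       t_ms = net$t_ms, schedule = net$schedule, stages = net$stages,
       rng = rng)
}

#' @rdname aec_state
#' @param state a list produced by `aec_state()`.
#' @export
aec_restore <- function(state) {
  net <- aec_network(state$config)
  eng_set_state(net$ptr, state$engine)
  net$t_ms <- state$t_ms
  net$schedule <- state$schedule
  net$stages <- state$stages
  if (!is.null(state$rng))
    assign(".Random.seed", state$rng, envir = globalenv())
  net
}

#' @export
print.aec_network <- function(x, ...) {
  g <- x$config$geometry
  cat(sprintf("aec_network (%s, %s scale)\n", x$config$task, x$config$scale))
  cat(sprintf("  simple %d cells in %d maps | complex %d cells | critic %d | actor %d\n",
              g$n_simple, g$s_maps, g$n_complex,
              x$config$rl$n_critic, 2 * x$config$rl$n_actor_per_action))
  cat(sprintf("  simulated time %.3f s; stages run: %s\n", x$t_ms / 1000,
              if (length(x$stages)) paste(x$stages, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
summary.aec_network <- function(object, ...) {
  st <- eng_status(object$ptr)
  w <- eng_get_weights(object$ptr)
  out <- list(
    task = object$config$task,
    t_s = object$t_ms / 1000,
    events = st$events, simple_spikes = st$simple,
    complex_spikes = st$complex,
    reduction_simple = if (st$simple > 0) st$events / st$simple else NA_real_,
    reduction_complex = if (st$complex > 0) st$events / st$complex else NA_real_,
    activity_S = st$S, event_rate_E = st$E,
    reward = st$R, value = st$V,
    mean_simple_weight = mean(unlist(w$simple_maps)),
    threshold_range = range(eng_thresholds(object$ptr))
  )
  class(out) <- "summary.aec_network"
  out
}

#' @export
print.summary.aec_network <- function(x, ...) {
  cat(sprintf("aec_network summary (%s), %.3f s simulated\n", x$task, x$t_s))
  cat(sprintf("  events %d | simple spikes %d (reduction %.1fx) | complex %d (%.1fx)\n",
              round(x$events), round(x$simple_spikes),
              x$reduction_simple, round(x$complex_spikes),
              x$reduction_complex))
  cat(sprintf("  activity S = %.2f /ms, event rate E = %.2f /ms, reward R = %.3f\n",
              x$activity_S, x$event_rate_E, x$reward))
  cat(sprintf("  value V = %.2f mV; simple thresholds in [%.2f, %.2f] mV\n",
              x$value, x$threshold_range[1], x$threshold_range[2]))
  invisible(x)
}

#' @describeIn aec_network `coef()` returns all learned weight tensors:
#'   `simple_maps` (one shared ON/OFF tensor per map), `complex`, `lateral`,
#'   `topdown`, `critic`, `actor`.
#' @param object,... S3 method arguments.
#' @export
coef.aec_network <- function(object, ...) {
  eng_get_weights(object$ptr)
}

#' Encode an event stream with a (trained) network
#'
#' Runs the encoder over a stream with all plasticity frozen and returns the
#' resulting spike counts: the sparse code the network assigns to the input.
#' The network's neuron states advance (the model is stateful), but no
#' weights change.
#'
#' @param object an [aec_network()].
#' @param stream an [event_stream()].
#' @param bin_ms width of the reporting bins (ms).
#' @param ... unused.
#' @return list with `per_cell` simple/complex spike counts, `bins`
#'   (data.frame of per-bin event and spike counts) and totals.
#' @export
predict.aec_network <- function(object, stream, bin_ms = 100, ...) {
  stopifnot(inherits(stream, "event_stream"))
  old <- eng_status(object$ptr)
  eng_set_flags(object$ptr, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  eng_reset_totals(object$ptr)
  counts0 <- eng_cell_counts(object$ptr, reset = TRUE)
  bins <- feed_stream(object, stream, bin_ms = bin_ms)
  counts <- eng_cell_counts(object$ptr, reset = FALSE)
  st <- eng_status(object$ptr)
  list(per_cell_simple = counts$simple, per_cell_complex = counts$complex,
       bins = bins, events = st$events, simple_spikes = st$simple,
       complex_spikes = st$complex)
}

# Replay a recorded stream `repeats` times back to back. The per-tick event
# schedule is computed once, so the cost per repetition is engine-bound.
# Returns one row of counts per repetition; advances net$t_ms.
replay_stream <- function(net, stream, repeats = 1) {
  if (nrow(stream) == 0 || repeats < 1)
    return(data.frame(bin = numeric(), events = numeric(),
                      simple = numeric(), complex = numeric()))
  rel <- stream$t / 1000
  n_ticks <- ceiling(max(rel))
  tick_of <- pmin(pmax(ceiling(rel), 1), n_ticks)
  ord <- order(tick_of, rel, stream$y, stream$x, stream$polarity)
  rel <- rel[ord]; tick_of <- tick_of[ord]
  x <- stream$x[ord]; y <- stream$y[ord]; pol <- stream$polarity[ord]
  res <- eng_replay(net$ptr, net$t_ms, rel, x, y, pol, n_ticks, repeats)
  net$t_ms <- res$t_end
  m <- res$counts
  data.frame(bin = seq_len(repeats), events = m[, 1], simple = m[, 2],
             complex = m[, 3])
}

# Feed a stream tick by tick (1 ms). Returns per-bin counts of events and
# simple/complex spikes. Advances net$t_ms past the end of the stream.
feed_stream <- function(net, stream, bin_ms = 100) {
  t0 <- net$t_ms
  if (nrow(stream) == 0) return(data.frame(bin = numeric(), events = numeric(),
                                           simple = numeric(), complex = numeric()))
  tms <- t0 + stream$t / 1000
  end <- ceiling(max(tms))
  n_ticks <- end - t0
  # assign events to 1 ms ticks: tick k covers (t0+k-1, t0+k]
  tick_of <- pmin(pmax(ceiling(tms - t0), 1), n_ticks)
  ord <- order(tick_of, tms, stream$y, stream$x, stream$polarity)
  tms <- tms[ord]; tick_of <- tick_of[ord]
  x <- stream$x[ord]; y <- stream$y[ord]; pol <- stream$polarity[ord]
  splits <- split(seq_along(tms), tick_of)
  bin_rows <- list()
  prev <- c(0, 0, 0)
  st0 <- eng_status(net$ptr)
  base <- c(st0$events, st0$simple, st0$complex)
  bin_id <- 0
  for (k in seq_len(n_ticks)) {
    idx <- splits[[as.character(k)]]
    if (!is.null(idx))
      eng_feed_events(net$ptr, tms[idx], x[idx], y[idx], pol[idx])
    eng_tick(net$ptr, t0 + k)
    if (k %% (bin_ms) == 0 || k == n_ticks) {
      st <- eng_status(net$ptr)
      cur <- c(st$events, st$simple, st$complex) - base
      bin_id <- bin_id + 1
      bin_rows[[bin_id]] <- c(bin_id, cur - prev)
      prev <- cur
    }
  }
  net$t_ms <- t0 + n_ticks
  m <- do.call(rbind, bin_rows)
  data.frame(bin = m[, 1], events = m[, 2], simple = m[, 3], complex = m[, 4])
}
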