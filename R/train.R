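#' Staged training and validation
#'
#' Runs one stage of the curriculum on a network, freezing exactly the
#' weight groups the stage dictates:
#'
#' * `"train-coding"` - learns the excitatory simple- and complex-cell
#'   weights on an event stream (plastic inhibition frozen). Provide a
#'   `stream` (e.g. from [synth_stream()]) or an `env` to generate input
#'   from the task world with periodic uniform resets.
#' * `"train-inhibition"` - freezes all excitatory weights and learns only
#'   the lateral and top-down inhibitory connections while the environment
#'   is reset from the center-biased (`"centered-normal"`) distribution.
#'   This shapes the activity profile that generates the intrinsic reward.
#' * `"train-agent"` - freezes the encoder and learns the critic and actor
#'   by reward-modulated STDP in closed loop, with the exploration /
#'   action-interval / learning-rate schedule decaying every `Delta_decay`.
#' * `"validate"` - closed loop with all plasticity off and pure
#'   exploitation (no exploration), resetting the stimulus periodically;
#'   records the angular-error trace.
#'
#' @param net an [aec_network()]; advanced in place.
#' @param stage one of `"train-coding"`, `"train-inhibition"`,
#'   `"train-agent"`, `"validate"`.
#' @param duration_s simulated duration in seconds.
#' @param env an [aec_env()] (created from the network's config if missing).
#' @param stream optional [event_stream()] input for `"train-coding"` or
#'   `"train-inhibition"`; training then runs on the recorded stream instead
#'   of the closed-loop world (much faster, and how the inhibition stage is
#'   meant to be driven: repeated presentations of a short recording).
#' @param repeats how many times the `stream` recording is replayed.
#' @param reset_every_ms interval between environment resets (defaults:
#'   500 coding/inhibition, 2000 agent and tracking validation, 1000
#'   stabilization validation).
#' @param explore_s for `"train-agent"`: duration (s) of the initial
#'   full-exploration phase, during which every action is random and only
#'   the critic weights are updated; the decaying schedule starts after it.
#' @param checkpoint_at fractions of the stage duration at which to capture
#'   full network states ([aec_state()]).
#' @param bin_ms metric bin width (ms).
#' @return an `aec_stage` list: `stage`, `metrics` (one row per action
#'   selection: `t_ms`, `action`, `explored`, `lambda_EXP`, `interval`, `V`,
#'   `delta`, `R`, `left`, `right`), `bins` (per-bin event/spike counts),
#'   `trace` (per-tick `t_ms`, `error`, `reset`), `checkpoints`, `net`.
#' @export
run_stage <- function(net, stage = c("train-coding", "train-inhibition",
                                     "train-agent", "validate"),
                      duration_s = 1, env = NULL, stream = NULL,
                      repeats = 1, reset_every_ms = NULL, explore_s = 0,
                      checkpoint_at = numeric(), bin_ms = 100) {
  stage <- match.arg(stage)
  stopifnot(inherits(net, "aec_network"))

  if (stage %in% c("train-coding", "train-inhibition") && !is.null(stream)) {
    if (stage == "train-coding")
      eng_set_flags(net$ptr, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
    else  # inhibition stage: the whole excitatory operating point is
          # frozen, including the adaptive thresholds
      eng_set_flags(net$ptr, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
    bins <- if (repeats > 1) replay_stream(net, stream, repeats)
            else feed_stream(net, stream, bin_ms = bin_ms)
    net$stages <- c(net$stages, stage)
    return(structure(list(stage = stage, metrics = NULL, bins = bins,
                          trace = NULL, checkpoints = list(), net = net),
                     class = "aec_stage"))
  }

  if (is.null(env)) env <- aec_env(net$config)
  if (is.null(reset_every_ms)) {
    reset_every_ms <- switch(stage,
      "train-coding" = 500, "train-inhibition" = 500,
      "train-agent" = 2000,
      "validate" = if (net$config$task == "tracking") 2000 else 1000)
  }
  flags <- switch(stage,
    "train-coding"     = list(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    "train-inhibition" = list(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    "train-agent"      = list(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    "validate"         = list(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  do.call(eng_set_flags, c(list(net$ptr), flags))
  reset_dist <- switch(stage,
    "train-coding" = "uniform", "train-inhibition" = "centered-normal",
    "train-agent" = "uniform", "validate" = "border")
  act <- stage %in% c("train-agent", "validate")

  n_ticks <- round(duration_s * 1000)
  t0 <- net$t_ms
  env_reset(env, reset_dist)
  sp <- env_speeds(env)
  envp <- list(
    task = env$task, width = env$width, height = env$height,
    fov_half = env$fov_half, error = env$error, gaze = env$gaze,
    drift_dir = env$drift_dir,
    ou_theta = net$config$env$ou_theta, ou_sigma = net$config$env$ou_sigma,
    cam_speed = sp$cam, drift_speed = sp$drift,
    ball_r = if (env$task == "tracking")
      net$config$env$ball_radius_frac * env$height else 0,
    n_stripes = if (env$task == "tracking") net$config$env$n_stripes else 0,
    n_bars = if (env$task == "tracking") 0 else net$config$env$n_bars,
    duty = if (env$task == "tracking") 0 else net$config$env$bar_duty,
    threshold = net$config$converter$threshold,
    I_floor = net$config$converter$I_floor)
  sch <- net$schedule
  ctrl <- list(
    t0 = t0, n_ticks = n_ticks, act = act,
    decay_schedule = (stage == "train-agent"),
    exit_resets = (stage == "train-agent"),
    reset_every_ms = as.integer(reset_every_ms),
    reset_dist = match(reset_dist,
                       c("uniform", "centered-normal", "border")) - 1L,
    action_interval = if (stage == "validate") sch$action_interval_min
                      else sch$action_interval,
    action_interval_min = sch$action_interval_min,
    lambda_EXP = if (stage == "validate") 0 else sch$lambda_EXP,
    eta_critic = sch$eta_critic, eta_actor = sch$eta_actor,
    eta_decay_critic = sch$eta_decay_critic,
    eta_decay_actor = sch$eta_decay_actor,
    Delta_decay = sch$Delta_decay,
    border_side = as.integer(env$border_side))

  # initial full-exploration phase: random actions, critic-only learning,
  # schedule frozen
  explore_ticks <- if (stage == "train-agent") round(explore_s * 1000) else 0
  explore_ticks <- min(explore_ticks, n_ticks)
  # run in segments so full network states can be captured at checkpoints
  ck <- sort(unique(round(checkpoint_at * n_ticks)))
  ck <- ck[ck > 0 & ck < n_ticks]
  seg_ends <- unique(sort(c(ck, explore_ticks, n_ticks)))
  seg_ends <- seg_ends[seg_ends > 0]
  checkpoints <- list()
  traces <- list(); metrics <- list()
  done <- 0
  st_prev <- eng_status(net$ptr)
  for (seg in seg_ends) {
    ctrl$t0 <- t0 + done
    ctrl$n_ticks <- as.integer(seg - done)
    in_explore <- (seg <= explore_ticks)
    ctrl_seg <- ctrl
    if (in_explore) {
      ctrl_seg$lambda_EXP <- 1
      ctrl_seg$eta_actor <- 0
      ctrl_seg$decay_schedule <- FALSE
    }
    out <- eng_closed_loop(net$ptr, envp, ctrl_seg)
    traces[[length(traces) + 1]] <-
      data.frame(t_ms = t0 + done + seq_len(seg - done),
                 error = out$trace_error,
                 reset = out$trace_reset > 0)
    if (length(out$m$t_ms) > 0)
      metrics[[length(metrics) + 1]] <- as.data.frame(out$m)
    # carry schedule and environment across segments
    if (!in_explore) {
      ctrl$lambda_EXP <- out$schedule$lambda_EXP
      ctrl$eta_critic <- out$schedule$eta_critic
      ctrl$eta_actor <- out$schedule$eta_actor
      ctrl$action_interval <- out$schedule$action_interval
    }
    ctrl$border_side <- as.integer(out$schedule$border_side)
    envp$error <- out$env$error
    envp$gaze <- out$env$gaze
    envp$drift_dir <- out$env$drift_dir
    done <- seg
    net$t_ms <- t0 + done
    if (stage == "train-agent") {
      sch$lambda_EXP <- ctrl$lambda_EXP
      sch$eta_critic <- ctrl$eta_critic
      sch$eta_actor <- ctrl$eta_actor
      sch$action_interval <- ctrl$action_interval
      net$schedule <- sch
    }
    if (done < n_ticks)
      checkpoints[[length(checkpoints) + 1]] <- aec_state(net)
  }
  env$error <- envp$error; env$gaze <- envp$gaze
  env$drift_dir <- envp$drift_dir; env$border_side <- ctrl$border_side
  env$t_ms <- env$t_ms + n_ticks
  trace <- do.call(rbind, traces)
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  if (!is.null(metrics)) {
    metrics$explored <- metrics$explored > 0
    metrics <- metrics[, c("t_ms", "action", "explored", "lambda_EXP",
                           "interval", "V", "delta", "R", "left", "right")]
  }
  st_now <- eng_status(net$ptr)
  bins <- data.frame(bin = 1, events = st_now$events - st_prev$events,
                     simple = st_now$simple - st_prev$simple,
                     complex = st_now$complex - st_prev$complex)
  net$stages <- c(net$stages, stage)
  structure(list(stage = stage, metrics = metrics, bins = bins,
                 trace = trace, checkpoints = checkpoints, net = net),
            class = "aec_stage")
}

#' @export
print.aec_stage <- function(x, ...) {
  cat(sprintf("aec_stage: %s\n", x$stage))
  if (!is.null(x$bins)) {
    cat(sprintf("  %d bins, %d events, %d simple / %d complex spikes\n",
                nrow(x$bins), round(sum(x$bins$events)),
                round(sum(x$bins$simple)), round(sum(x$bins$complex))))
  }
  if (!is.null(x$metrics))
    cat(sprintf("  %d action selections, final V = %.2f, mean R = %.3f\n",
                nrow(x$metrics), x$metrics$V[nrow(x$metrics)],
                mean(x$metrics$R)))
  invisible(x)
}

#' Sparsification and input-tracking summary
#'
#' Computes, from the per-bin counters of a stage, the activity-reduction
#' factors (input events per simple-cell spike and per complex-cell spike)
#' and the per-bin Pearson correlation between event counts and simple-cell
#' spike counts - the measures used to judge coding efficiency.
#'
#' @param bins the `bins` data.frame of an `aec_stage` (or of
#'   [predict.aec_network()]).
#' @return list with `reduction_simple`, `reduction_complex`,
#'   `correlation`, `events`, `simple`, `complex`.
#' @export
sparsity_summary <- function(bins) {
  stopifnot(all(c("events", "simple", "complex") %in% names(bins)))
  ev <- sum(bins$events); si <- sum(bins$simple); co <- sum(bins$complex)
  corr <- if (nrow(bins) >= 3 && stats::sd(bins$simple) > 0 &&
              stats::sd(bins$events) > 0)
    stats::cor(bins$events, bins$simple) else NA_real_
  list(reduction_simple = if (si > 0) ev / si else Inf,
       reduction_complex = if (co > 0) ev / co else Inf,
       correlation = corr, events = ev, simple = si, complex = co)
}

#' Return-to-center performance of a validation run
#'
#' Scores a `"validate"` stage: after every reset, did the agent bring the
#' angular error back below `tol` within `within_ms`, and did it do so
#' before the next reset?
#'
#' @param trace the `trace` data.frame of a `"validate"` [run_stage()].
#' @param tol error tolerance (rad).
#' @param within_ms time allowed after each reset (ms).
#' @param settle_ms the error must stay below `tol` for at least one tick
#'   within the window (first crossing counts).
#' @return list with `n_resets`, `n_returned`, `return_rate`,
#'   `mean_abs_error`.
#' @export
return_rate <- function(trace, tol, within_ms = 1000, settle_ms = 0) {
  resets <- which(trace$reset)
  if (length(resets) == 0)
    return(list(n_resets = 0, n_returned = 0, return_rate = NA_real_,
                mean_abs_error = mean(abs(trace$error))))
  n_ret <- 0
  for (r in resets) {
    w <- trace$error[seq(r + 1, min(r + within_ms, nrow(trace)))]
    if (length(w) >= 50 && any(abs(w) < tol)) n_ret <- n_ret + 1
  }
  list(n_resets = length(resets), n_returned = n_ret,
       return_rate = n_ret / length(resets),
       mean_abs_error = mean(abs(trace$error)))
}

#' Shuffle the learned inhibitory weights (control network)
#'
#' Builds the control condition for the inhibition experiments: each simple
#' cell's incoming lateral and top-down weight vectors are permuted
#' uniformly at random (R RNG), preserving the per-cell weight totals while
#' destroying the learned source structure.
#'
#' @param net an [aec_network()]; modified in place and returned invisibly.
#' @export
shuffle_inhibition <- function(net) {
  stopifnot(inherits(net, "aec_network"))
  eng_shuffle_inhibition(net$ptr)
  invisible(net)
}

#' Summary report of a training run
#'
#' Collects the headline numbers of a sequence of stage results into one
#' printable list: sparsification, correlation, reward statistics and
#' (when present) validation return rates.
#'
#' @param ... `aec_stage` results.
#' @param tol error tolerance (rad) for the validation score.
#' @return an `aec_report` list.
#' @export
aec_report <- function(..., tol = 0.1) {
  stages <- list(...)
  out <- list()
  for (s in stages) {
    if (!inherits(s, "aec_stage")) next
    entry <- list(stage = s$stage)
    if (!is.null(s$bins)) entry$sparsity <- sparsity_summary(s$bins)
    if (!is.null(s$metrics)) {
      entry$mean_reward <- mean(s$metrics$R)
      entry$final_value <- s$metrics$V[nrow(s$metrics)]
    }
    if (identical(s$stage, "validate") && !is.null(s$trace))
      entry$performance <- return_rate(s$trace, tol = tol)
    out[[length(out) + 1]] <- entry
  }
  structure(out, class = "aec_report")
}

#' @export
print.aec_report <- function(x, ...) {
  for (e in x) {
    cat(sprintf("== %s ==\n", e$stage))
    if (!is.null(e$sparsity))
      cat(sprintf("  reduction %.1fx simple / %.1fx complex, correlation %.3f\n",
                  e$sparsity$reduction_simple, e$sparsity$reduction_complex,
                  e$sparsity$correlation))
    if (!is.null(e$mean_reward))
      cat(sprintf("  mean reward %.3f, final value %.2f\n",
                  e$mean_reward, e$final_value))
    if (!is.null(e$performance))
      cat(sprintf("  resets %d, returned %d (%.0f%%), mean |error| %.3f rad\n",
                  e$performance$n_resets, e$performance$n_returned,
                  100 * e$performance$return_rate,
                  e$performance$mean_abs_error))
  }
  invisible(x)
}

#' Inhibition-frequency experiment
#'
#' Reproduces the core relationship between stimulus frequency and network
#' activity. The plastic lateral and top-down inhibitory connections are
#' trained (excitatory weights and thresholds frozen) on many repetitions of
#' a short recording whose stimulus positions (tracking) or orientations
#' (stabilization) follow a center-biased distribution. A deterministic sweep
#' of the stimulus across the full range is then presented twice: once to the
#' trained network, once to a control with the inhibitory weights shuffled
#' uniformly at random within each tensor. Frequently seen (central) stimuli
#' should evoke markedly less activity in the trained network, and the
#' control-minus-experiment difference profile should peak where the
#' training density was highest.
#'
#' @param net an [aec_network()] whose encoder has been trained
#'   (`"train-coding"`); modified in place (inhibition is learned).
#' @param recording_ms length of the short recording (ms).
#' @param repeats how many times the recording is replayed.
#' @param n_bins sweep bins.
#' @param pass_ms,passes sweep speed and repetitions (see
#'   [validation_sweep()]).
#' @return list with `profile` (data.frame: `center`, `experiment`,
#'   `control`, `difference`), `center_ratio` (central-third activity,
#'   experiment / control), `peak_bin`, `central_bins`, and the sweeps.
#' @export
inhibition_experiment <- function(net, recording_ms = 2000, repeats = 3000,
                                  n_bins = 15, pass_ms = 600, passes = 3) {
  stopifnot(inherits(net, "aec_network"))
  cfg <- net$config
  rec <- synth_stream("center-osc", cfg, recording_ms, time_jitter = FALSE)
  run_stage(net, "train-inhibition", stream = rec, repeats = repeats)
  snap <- aec_state(net)
  sw_exp <- validation_sweep(net, aec_env(cfg), n_bins = n_bins,
                             pass_ms = pass_ms, passes = passes, rl = FALSE)
  ctl <- aec_restore(snap)
  shuffle_inhibition(ctl)
  sw_ctl <- validation_sweep(ctl, aec_env(cfg), n_bins = n_bins,
                             pass_ms = pass_ms, passes = passes, rl = FALSE)
  eng_set_state(net$ptr, snap$engine)  # back to the post-training state
  net$t_ms <- snap$t_ms
  a_exp <- sw_exp$simple + sw_exp$complex
  a_ctl <- sw_ctl$simple + sw_ctl$complex
  thirds <- round(n_bins / 3)
  central <- (thirds + 1):(n_bins - thirds)
  d <- a_ctl - a_exp
  # light 3-bin smoothing stabilizes the argmax of the difference profile
  dsm <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  dsm[is.na(dsm)] <- d[is.na(dsm)]
  list(profile = data.frame(center = sw_exp$center, experiment = a_exp,
                            control = a_ctl, difference = d),
       center_ratio = sum(a_exp[central]) / sum(a_ctl[central]),
       peak_bin = which.max(dsm), central_bins = central,
       sweep_experiment = sw_exp, sweep_control = sw_ctl)
}

#' Critic recovery on a two-state toy problem
#'
#' Parameter-recovery check for the continuous-time TD critic, independent of
#' the visual front end. Two states are coded by disjoint Poisson-firing
#' subsets of the representation layer; each state carries a programmed
#' reward. At the steady state of the continuous TD rule the self-consistent
#' value of a state with constant reward `r` is `tau_r * r`, so after
#' training the decoded value difference `V(A) - V(B)` should approach
#' `tau_r * (r_A - r_B)` and the TD error should average to about zero.
#'
#' @param config an [aec_config()] (a small topology is enough; only the
#'   critic population matters).
#' @param r_A,r_B programmed rewards of the two states.
#' @param rate_hz Poisson rate of each active source cell.
#' @param n_per_state number of source cells coding each state.
#' @param train_s training duration (s); states alternate every `episode_ms`.
#' @param probe_s duration of the frozen-weight probe of each state (s).
#' @param episode_ms length of one state visit during training (ms).
#' @return list with `V_A`, `V_B`, `difference`, `analytic`
#'   (`tau_r * (r_A - r_B)`), `mean_delta_late` (mean TD error over the last
#'   quarter of training), `values` (probe value series).
#' @export
critic_recovery_experiment <- function(config = aec_config("tracking", "desk"),
                                       r_A = 15, r_B = 5, rate_hz = 60,
                                       n_per_state = 12, train_s = 80,
                                       probe_s = 3, episode_ms = 1000) {
  net <- aec_network(config)
  tau_r <- config$rl$tau_r
  eng_set_flags(net$ptr, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  src_A <- seq_len(n_per_state) - 1L
  src_B <- n_per_state + seq_len(n_per_state) - 1L
  p_spike <- rate_hz / 1000
  eta_now <- config$critic$eta
  run_block <- function(t0, n_ms, state, learn, action_every = 250,
                        collect = FALSE) {
    eng_set_reward_override(net$ptr, TRUE, if (state == "A") r_A else r_B)
    src <- if (state == "A") src_A else src_B
    deltas <- if (collect) numeric(n_ms) else NULL
    vals <- if (collect) numeric(n_ms) else NULL
    for (k in seq_len(n_ms)) {
      t <- t0 + k
      n_sp <- stats::rpois(1, p_spike * length(src))
      if (n_sp > 0) {
        who <- src[sample.int(length(src), n_sp, replace = TRUE)]
        eng_inject_spikes(net$ptr, who, rep(t - 0.5, n_sp))
      }
      eng_tick(net$ptr, t)
      if (learn && k %% action_every == 0)
        eng_action_step(net$ptr, t, 1, eta_now, 0)
      if (collect) {
        st <- eng_status(net$ptr)
        deltas[k] <- st$delta; vals[k] <- st$V
      }
    }
    net$t_ms <- t0 + n_ms
    list(deltas = deltas, vals = vals)
  }
  n_ep <- ceiling(train_s * 1000 / episode_ms)
  late_deltas <- numeric(0)
  eta_c <- config$critic$eta
  decay_every <- config$rl$Delta_decay
  next_decay <- decay_every
  for (ep in seq_len(n_ep)) {
    state <- if (ep %% 2 == 1) "A" else "B"
    collect <- ep > 0.75 * n_ep
    eta_now <- eta_c
    out <- run_block(net$t_ms, episode_ms, state, learn = TRUE,
                     collect = collect)
    while (net$t_ms >= next_decay) {   # learning-rate decay schedule
      eta_c <- eta_c * (1 - config$critic$eta_decay / 100)
      next_decay <- next_decay + decay_every
    }
    if (collect)  # skip the transient after each state switch
      late_deltas <- c(late_deltas, out$deltas[-seq_len(200)])
  }
  eng_set_flags(net$ptr, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  pa <- run_block(net$t_ms, probe_s * 1000, "A", learn = FALSE,
                  collect = TRUE)
  pb <- run_block(net$t_ms, probe_s * 1000, "B", learn = FALSE,
                  collect = TRUE)
  drop <- seq_len(500)  # settle after the switch
  V_A <- mean(pa$vals[-drop]); V_B <- mean(pb$vals[-drop])
  eng_set_reward_override(net$ptr, FALSE, 0)
  list(V_A = V_A, V_B = V_B, difference = V_A - V_B,
       analytic = tau_r * (r_A - r_B),
       mean_delta_late = mean(late_deltas),
       sd_delta_late = stats::sd(late_deltas),
       values = list(A = pa$vals, B = pb$vals))
}

#' @describeIn run_stage `plot()` of a stage result shows the angular-error
#'   trace with reset markers (for stages with a trace) and the per-action
#'   value and reward series (when actions were taken).
#' @param x an `aec_stage`.
#' @param ... unused.
#' @export
plot.aec_stage <- function(x, ...) {
  has_trace <- !is.null(x$trace)
  has_m <- !is.null(x$metrics)
  op <- graphics::par(mfrow = c(has_trace + has_m, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (has_trace) {
    graphics::plot(x$trace$t_ms / 1000, x$trace$error * 180 / pi,
                   type = "l", xlab = "time (s)",
                   ylab = "angular error (deg)", main = x$stage)
    graphics::abline(v = x$trace$t_ms[x$trace$reset] / 1000,
                     col = "red", lty = 2)
    graphics::abline(h = 0, col = "grey")
  }
  if (has_m) {
    graphics::matplot(x$metrics$t_ms / 1000,
                      cbind(x$metrics$V, x$metrics$R), type = "l",
                      lty = 1, col = c("black", "purple"),
                      xlab = "time (s)", ylab = "V / R")
    graphics::legend("topright", c("value", "reward"),
                     col = c("black", "purple"), lty = 1, bty = "n")
  }
  invisible(x)
}
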