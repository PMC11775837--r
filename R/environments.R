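#' Synthetic closed-loop environments
#'
#' Two worlds rendered at 1 kHz and converted to events by the log-threshold
#' emulator:
#'
#' * **tracking** - a striped ball translates horizontally across the field
#'   of a camera that can rotate about one (vertical) axis; the behavioural
#'   goal is to keep the ball centered. The angular error is the ball bearing
#'   relative to gaze, wrapped to `(-pi, pi]`.
#' * **stabilization** - a bar grating rotates about the optical axis; the
#'   goal is to keep the bars horizontal. The orientation error is
#'   pi-periodic, wrapped to `(-pi/2, pi/2]`.
#'
#' The camera additionally jitters via an Ornstein-Uhlenbeck process applied
#' to its pose before rendering (emulating fixational eye movements), which
#' sustains event generation even for slow stimuli.
#'
#' Actions are two symmetric angular velocities (left/right, or clockwise/
#' counter-clockwise) applied between action selections.
#'
#' @param config an [aec_config()]; task and geometry are taken from it.
#' @return an `aec_env` (mutable environment object).
#' @examples
#' env <- aec_env(aec_config("tracking", scale = "desk"))
#' f <- render_tick(env)
#' dim(f)  # height x width luminance frame
#' @export
aec_env <- function(config = aec_config()) {
  e <- new.env(parent = emptyenv())
  e$task <- config$task
  e$cfg <- config
  g <- config$geometry
  e$width <- g$width; e$height <- g$height
  e$fov_half <- if (config$task == "tracking") pi / 3 else pi / 2
  e$error <- 0             # rad: ball bearing - gaze, or grating orientation
  e$gaze <- 0              # rad: camera pan (tracking) / roll (stabilization)
  e$drift_dir <- 1         # autonomous stimulus motion direction
  e$action_vel <- 0        # rad/s currently applied by the agent
  e$ou <- ou_state(c(0, 0), theta = config$env$ou_theta,
                   mu = config$env$ou_mu, sigma = config$env$ou_sigma)
  e$t_ms <- 0
  e$border_side <- 1
  class(e) <- "aec_env"
  e
}

#' @export
print.aec_env <- function(x, ...) {
  cat(sprintf("aec_env: %s, error %.3f rad, t = %.3f s\n",
              x$task, x$error, x$t_ms / 1000))
  invisible(x)
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi
wrap_half_pi <- function(a) ((a + pi / 2) %% pi) - pi / 2

# per-task conversion: action authority and stimulus drift in rad/s
env_speeds <- function(e) {
  if (e$task == "tracking") {
    field <- 2 * e$fov_half
    list(cam = e$cfg$env$cam_speed * field,
         drift = e$cfg$env$ball_speed * field)
  } else {
    list(cam = e$cfg$env$cam_speed * pi / 180,
         drift = e$cfg$env$grating_speed * pi / 180)
  }
}

#' Reset the environment error
#'
#' Draws a new angular error. `"centered-normal"` (sd = one sixth of the
#' error range) is the biased distribution used when training the
#' inhibition; `"uniform"` covers the range; `"border"` alternates between
#' the left and right (or extreme-orientation) edges, as in validation.
#'
#' @param e an [aec_env()].
#' @param distribution reset distribution.
#' @param value optional explicit error (rad), overrides the draw.
#' @return the environment, invisibly.
#' @export
env_reset <- function(e, distribution = c("uniform", "centered-normal",
                                          "border"), value = NULL) {
  distribution <- match.arg(distribution)
  half <- if (e$task == "tracking") e$fov_half else pi / 2
  if (!is.null(value)) {
    e$error <- value
  } else if (distribution == "uniform") {
    e$error <- stats::runif(1, -0.9 * half, 0.9 * half)
  } else if (distribution == "centered-normal") {
    e$error <- max(-0.9 * half, min(0.9 * half, stats::rnorm(1, 0, half / 3)))
  } else {
    e$error <- 0.85 * half * e$border_side
    e$border_side <- -e$border_side
  }
  e$drift_dir <- if (stats::runif(1) < 0.5) -1 else 1
  invisible(e)
}

#' Advance the environment by one tick
#'
#' Applies one `dt_ms` step of the stimulus drift, the agent's current
#' angular velocity and the Ornstein-Uhlenbeck camera jitter, then re-wraps
#' the angular error. `action` switches the commanded velocity: 1 rotates
#' the camera left (counter-clockwise), 2 right (clockwise), 0 disables
#' actions, `NULL` keeps the previous command.
#'
#' @param e an [aec_env()].
#' @param action `NULL`, 0, 1 or 2.
#' @param dt_ms step in milliseconds.
#' @param drift logical: advance the autonomous stimulus motion?
#' @return the environment, invisibly.
#' @export
env_step <- function(e, action = NULL, dt_ms = 1, drift = TRUE) {
  sp <- env_speeds(e)
  if (!is.null(action)) {
    if (!(action %in% 0:2)) stop("unknown action id: ", action)
    e$action_vel <- c(0, -sp$cam, sp$cam)[action + 1]
  }
  if (dt_ms == 0) return(invisible(e))   # command change only
  dt <- dt_ms / 1000
  e$gaze <- e$gaze + e$action_vel * dt
  derr <- -e$action_vel * dt
  if (drift) derr <- derr + e$drift_dir * sp$drift * dt
  e$error <- if (e$task == "tracking") wrap_pi(e$error + derr)
             else wrap_half_pi(e$error + derr)
  e$ou <- ou_step(e$ou, dt)
  e$t_ms <- e$t_ms + dt_ms
  invisible(e)
}

#' Render the current luminance frame
#'
#' Deterministic rasterization of the stimulus at the current angular error
#' plus the camera-jitter offset: a striped disk on a plain background
#' (tracking) or white bars on a dark background behind a circular aperture
#' (stabilization). Luminances are in `[0.1, 1]`.
#'
#' @param e an [aec_env()].
#' @return `height x width` luminance matrix.
#' @export
render_tick <- function(e) {
  W <- e$width; H <- e$height
  jx <- e$ou$position[1]; jy <- e$ou$position[2]
  if (e$task == "tracking") {
    # ball center in pixels from the angular error
    cx <- (e$error / e$fov_half) * (W / 2) + W / 2 + jx
    cy <- H / 2 + jy
    r <- e$cfg$env$ball_radius_frac * H
    xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
    ys <- matrix(seq_len(H) - 0.5, H, W)
    inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    stripe_w <- 2 * r / e$cfg$env$n_stripes
    band <- floor((xs - cx + r) / stripe_w) %% 2
    # world-fixed background texture (sparse dots): camera pan and jitter
    # sweep it across the retina, so the event rate and baseline population
    # activity stay high wherever the target is - like a cluttered room
    gaze_px <- (e$gaze / e$fov_half) * (W / 2)
    xi <- floor(xs - 0.5 + gaze_px + jx)
    yi <- floor(ys - 0.5 + jy)
    dots <- ((7 * xi + 13 * yi) %% 19) == 0
    f <- matrix(0.1, H, W)
    f[dots] <- 0.35
    f[inside & band == 0] <- 1
    f[inside & band == 1] <- 0.4
    f
  } else {
    xs <- matrix(seq_len(W) - 0.5 - W / 2 - jx, H, W, byrow = TRUE)
    ys <- matrix(seq_len(H) - 0.5 - H / 2 - jy, H, W)
    # grating orientated at `error` from horizontal
    yr <- -xs * sin(e$error) + ys * cos(e$error)
    period <- H / e$cfg$env$n_bars
    phase <- (yr / period) %% 1
    f <- matrix(0.1, H, W)
    # world-fixed dot texture outside the aperture, rotating with the camera
    xr <- xs * cos(e$error) + ys * sin(e$error)
    xi <- floor(xr); yi <- floor(yr)
    dots <- ((7 * xi + 13 * yi) %% 19) == 0
    f[dots] <- 0.35
    mask <- xs^2 + ys^2 <= (0.45 * min(W, H))^2
    f[mask] <- 0.1
    f[mask & (phase < e$cfg$env$bar_duty)] <- 1
    f
  }
}

#' Scripted validation sweep
#'
#' Moves the stimulus deterministically across the whole state range with
#' actions disabled - the ball once left to right and back (tracking), or
#' the grating from -90 deg to +90 deg and back (stabilization) - while the
#' network observes. Critic, per-group actor and simple-cell spikes are
#' binned by stimulus position/orientation.
#'
#' @param net an [aec_network()].
#' @param env an [aec_env()] (matching task); its state is advanced.
#' @param n_bins number of position/orientation bins.
#' @param pass_ms duration of one directional pass (ms).
#' @param passes number of back-and-forth pass pairs to accumulate.
#' @param ou logical: keep camera jitter on during the sweep?
#' @param rl logical: run the critic/actor populations (disable to measure
#'   encoder activity only, e.g. in the inhibition experiments).
#' @return an `aec_sweep` data.frame: one row per bin with `bin`, `center`
#'   (rad), `events`, `simple`, `complex`, `critic`, `actor_left`,
#'   `actor_right`, `visits`.
#' @export
validation_sweep <- function(net, env, n_bins = 15, pass_ms = 1000,
                             passes = 1, ou = TRUE, rl = TRUE) {
  stopifnot(inherits(net, "aec_network"), inherits(env, "aec_env"))
  eng_set_flags(net$ptr, FALSE, FALSE, FALSE, FALSE, rl, FALSE)
  half <- if (env$task == "tracking") 0.85 * env$fov_half else pi / 2
  edges <- seq(-half, half, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  acc <- matrix(0, n_bins, 7,
                dimnames = list(NULL, c("events", "simple", "complex",
                                        "critic", "actor_left", "actor_right",
                                        "visits")))
  conv <- event_converter(env$width, env$height,
                          net$config$converter$threshold,
                          net$config$converter$I_floor)
  if (!ou) env$ou$sigma <- 0
  n_rl <- net$config$rl$n_critic + 2 * net$config$rl$n_actor_per_action
  nc <- net$config$rl$n_critic
  npa <- net$config$rl$n_actor_per_action
  eng_cell_counts(net$ptr, reset = TRUE)
  prev <- eng_status(net$ptr)
  prev_counts <- eng_cell_counts(net$ptr, reset = FALSE)
  # pairs of passes: low -> high, then high -> low
  path <- rep(c(seq(-half, half, length.out = pass_ms),
                seq(half, -half, length.out = pass_ms)), passes)
  t0 <- net$t_ms
  for (k in seq_along(path)) {
    env$error <- path[k]
    env_step(env, action = 0, dt_ms = 1, drift = FALSE)
    env$error <- path[k]      # scripted: drift and action fully overridden
    t_ms <- t0 + k
    ev <- convert_step(conv, render_tick(env), t_ms * 1000)
    if (nrow(ev) > 0)
      eng_feed_events(net$ptr, ev$t / 1000, ev$x, ev$y, ev$polarity)
    eng_tick(net$ptr, t_ms)
    b <- findInterval(path[k], edges, rightmost.closed = TRUE)
    b <- min(max(b, 1), n_bins)
    st <- eng_status(net$ptr)
    cts <- eng_cell_counts(net$ptr, reset = FALSE)
    d_ev <- st$events - prev$events
    d_s <- st$simple - prev$simple
    d_c <- st$complex - prev$complex
    rl_prev <- prev_counts$rl; rl_now <- cts$rl
    d_rl <- rl_now - rl_prev
    acc[b, ] <- acc[b, ] + c(d_ev, d_s, d_c,
                             sum(d_rl[seq_len(nc)]),
                             sum(d_rl[nc + seq_len(npa)]),
                             sum(d_rl[nc + npa + seq_len(npa)]), 1)
    prev <- st
    prev_counts <- cts
  }
  net$t_ms <- t0 + length(path)
  out <- data.frame(bin = seq_len(n_bins), center = centers, acc)
  class(out) <- c("aec_sweep", "data.frame")
  out
}

#' @export
plot.aec_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$center, x$simple / pmax(x$visits, 1), type = "b",
                 xlab = "stimulus position (rad)",
                 ylab = "simple spikes / ms", main = "population activity")
  graphics::matplot(x$center,
                    cbind(x$actor_left, x$actor_right) / pmax(x$visits, 1),
                    type = "b", pch = 1:2, col = c("blue", "orange"),
                    xlab = "stimulus position (rad)",
                    ylab = "actor spikes / ms", main = "policy")
  graphics::legend("top", c("left", "right"), col = c("blue", "orange"),
                   lty = 1:2, bty = "n")
  invisible(x)
}
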