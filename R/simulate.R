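#' Generate synthetic event streams
#'
#' Renders a moving stimulus at 1 kHz with Ornstein-Uhlenbeck camera jitter
#' and converts it to events with the log-threshold emulator - the same
#' pipeline the closed-loop environments use, packaged as a plain stream
#' generator for training and testing the encoder. Randomness (jitter,
#' reset draws, event-time jitter) comes from R's RNG.
#'
#' @param kind stimulus type: `"moving-bar"` (a vertical bright bar sweeping
#'   back and forth; the canonical encoder-training stimulus), `"ball"` (the
#'   tracking stimulus drifting across the field with periodic resets),
#'   `"grating"` (the stabilization stimulus rotating continuously), or
#'   `"center-osc"` (the stimulus oscillating rapidly about the center with
#'   per-half-cycle amplitudes proportional to `|N(0, sd)|`, so stimulus
#'   positions/orientations follow the center-biased density used to train
#'   the inhibition).
#' @param config an [aec_config()]; geometry and emulator settings are taken
#'   from it.
#' @param duration_ms stream duration in milliseconds.
#' @param reset_every_ms for `"ball"`: interval between resets.
#' @param reset_distribution for `"ball"`: reset distribution passed to
#'   [env_reset()] (`"centered-normal"` gives the center-biased statistics
#'   used to train the inhibition).
#' @param time_jitter logical: apply event-time jitter of the configured
#'   window after conversion?
#' @return an [event_stream()].
#' @examples
#' set.seed(1)
#' s <- synth_stream("moving-bar", aec_config("tracking", "desk"), 200)
#' @export
synth_stream <- function(kind = c("moving-bar", "ball", "grating",
                                  "center-osc"),
                         config = aec_config(), duration_ms = 1000,
                         reset_every_ms = 500,
                         reset_distribution = "uniform",
                         time_jitter = TRUE) {
  kind <- match.arg(kind)
  g <- config$geometry
  W <- g$width; H <- g$height
  conv <- event_converter(W, H, config$converter$threshold,
                          config$converter$I_floor)
  chunks <- vector("list", duration_ms)
  if (kind == "moving-bar") {
    ou <- ou_state(c(0, 0), theta = config$env$ou_theta,
                   mu = 0, sigma = config$env$ou_sigma)
    xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
    # one pass = half a sweep period; speed and width vary per pass so the
    # maps see diverse stimulus statistics and the event rate fluctuates
    base <- config$env$bar_period_ms
    pass_len <- max(50, round(base / 2 * stats::runif(1, 0.5, 1.8)))
    bar_w <- sample(2:max(3, round(W / 20)), 1)
    k_pass <- 0; dir <- 1
    for (k in seq_len(duration_ms)) {
      k_pass <- k_pass + 1
      if (k_pass > pass_len) {
        k_pass <- 1; dir <- -dir
        pass_len <- max(50, round(base / 2 * stats::runif(1, 0.5, 1.8)))
        bar_w <- sample(2:max(3, round(W / 20)), 1)
      }
      ph <- k_pass / pass_len
      if (dir < 0) ph <- 1 - ph
      pos <- ph * (W - bar_w) + bar_w / 2 + ou$position[1]
      f <- matrix(0.1, H, W)
      f[abs(xs - pos) <= bar_w / 2] <- 1
      chunks[[k]] <- convert_step(conv, f, k * 1000)
      ou <- ou_step(ou, 0.001)
    }
  } else if (kind == "center-osc") {
    # the stimulus moves at constant speed toward successive targets drawn
    # from the centered normal (sd = range/3): back-and-forth motion around
    # the center whose position density is center-peaked, with edge speeds
    # fast enough for neighboring cells to fire within the STDP windows
    env <- aec_env(config)
    range_half <- 0.85 * (if (config$task == "tracking") env$fov_half
                          else pi / 2)
    v <- 8 * range_half / 1000           # rad per ms
    pos <- 0
    target <- max(-range_half, min(range_half,
                                   stats::rnorm(1, 0, range_half / 3)))
    for (k in seq_len(duration_ms)) {
      if (abs(target - pos) <= v)
        target <- max(-range_half, min(range_half,
                                       stats::rnorm(1, 0, range_half / 3)))
      pos <- pos + sign(target - pos) * v
      env$error <- pos
      env$ou <- ou_step(env$ou, 0.001)
      chunks[[k]] <- convert_step(conv, render_tick(env), k * 1000)
      env$t_ms <- env$t_ms + 1
    }
  } else {
    env <- aec_env(config)
    env_reset(env, reset_distribution)
    for (k in seq_len(duration_ms)) {
      if (kind == "ball" && k %% reset_every_ms == 0)
        env_reset(env, reset_distribution)
      env_step(env, action = 0, dt_ms = 1)
      chunks[[k]] <- convert_step(conv, render_tick(env), k * 1000)
    }
  }
  df <- do.call(rbind, lapply(chunks, as.data.frame))
  s <- event_stream(df$t, df$x, df$y, df$polarity, width = W, height = H)
  if (time_jitter && config$converter$jitter_us > 0)
    s <- jitter_event_times(s, config$converter$jitter_us)
  s
}
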