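#' Event streams
#'
#' An event stream is the native output of an event-based (DVS-style) camera:
#' a time-ordered sequence of per-pixel polarity changes. Each event is a row
#' `(t, x, y, polarity)` with `t` in integer microseconds, 0-based pixel
#' coordinates and polarity 1 (ON, brightness increase) or 0 (OFF, decrease).
#'
#' @param t integer timestamps in microseconds, non-negative.
#' @param x,y 0-based pixel coordinates, `0 <= x < width`, `0 <= y < height`.
#' @param polarity 0/1 vector (0 = OFF, 1 = ON).
#' @param width,height sensor geometry in pixels.
#' @return An `event_stream`: a data.frame with columns `t`, `x`, `y`,
#'   `polarity` and attributes `width`, `height`, sorted by `t` (ties broken
#'   by `y`, `x`, `polarity` for determinism).
#' @examples
#' ev <- event_stream(t = c(10, 5), x = c(1, 2), y = c(0, 0),
#'                    polarity = c(1, 0), width = 4, height = 2)
#' ev$t  # sorted: 5, 10
#' @export
event_stream <- function(t = integer(), x = integer(), y = integer(),
                         polarity = integer(), width, height) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(polarity) == n,
            width >= 1, height >= 1)
  if (n > 0) {
    if (any(t < 0)) stop("negative timestamps")
    if (any(x < 0 | x >= width)) stop("x coordinate outside sensor geometry")
    if (any(y < 0 | y >= height)) stop("y coordinate outside sensor geometry")
    if (any(!(polarity %in% c(0, 1)))) stop("polarity must be 0 or 1")
  }
  df <- data.frame(t = as.double(t), x = as.integer(x), y = as.integer(y),
                   polarity = as.integer(polarity))
  if (n > 1) {
    o <- order(df$t, df$y, df$x, df$polarity)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "width") <- as.integer(width)
  attr(df, "height") <- as.integer(height)
  class(df) <- c("event_stream", "data.frame")
  df
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("event_stream: %d events, %dx%d sensor", nrow(x),
              attr(x, "width"), attr(x, "height")))
  if (nrow(x) > 0)
    cat(sprintf(", t in [%d, %d] us", min(x$t), max(x$t)))
  cat("\n")
  invisible(x)
}

#' Read and write event streams as CSV
#'
#' The on-disk format is a plain CSV: a first comment line `# width,height`
#' carrying the sensor geometry, then rows `t_us,x,y,polarity` with polarity
#' in {0,1}. The round trip `read_events(write_events(s, f))` is lossless.
#'
#' @param path file path.
#' @return `read_events` returns an [event_stream()]; `write_events` returns
#'   `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing geometry header line")
  geo <- as.integer(strsplit(sub("^#\\s*", "", header), ",")[[1]])
  if (length(geo) != 2 || anyNA(geo)) stop("malformed geometry header")
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("numeric", "integer", "integer", "integer"))
  expected <- c("t_us", "x", "y", "polarity")
  if (!identical(names(df), expected)) stop("malformed column header")
  bad <- which(df$x < 0 | df$x >= geo[1] | df$y < 0 | df$y >= geo[2] |
                 !(df$polarity %in% c(0, 1)) | df$t_us < 0)
  if (length(bad) > 0)
    stop("invalid event at data row ", bad[1])
  event_stream(df$t_us, df$x, df$y, df$polarity,
               width = geo[1], height = geo[2])
}

#' @rdname read_events
#' @param stream an [event_stream()].
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d,%d", attr(stream, "width"), attr(stream, "height")),
             con)
  df <- data.frame(t_us = format(stream$t, scientific = FALSE, trim = TRUE),
                   x = stream$x, y = stream$y, polarity = stream$polarity)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Jitter event timestamps
#'
#' Perturbs every timestamp by an independent uniform draw in
#' `[-window/2, +window/2]` microseconds, clamps at zero and re-sorts. This
#' undoes the artificial clustering of emulated events at frame boundaries.
#' Coordinates, polarities and the event count are unchanged.
#'
#' @param stream an [event_stream()].
#' @param window jitter window in microseconds (> 0; 0 returns the input).
#' @return a jittered [event_stream()].
#' @export
jitter_event_times <- function(stream, window) {
  stopifnot(inherits(stream, "event_stream"), window >= 0)
  if (window == 0 || nrow(stream) == 0) return(stream)
  t2 <- round(stream$t + stats::runif(nrow(stream), -window / 2, window / 2))
  t2 <- pmax(t2, 0)
  event_stream(t2, stream$x, stream$y, stream$polarity,
               width = attr(stream, "width"), height = attr(stream, "height"))
}

#' Stateful frame-to-event converter
#'
#' Emulates an event camera from a high-rate (1 kHz) luminance frame sequence:
#' each pixel holds the log-intensity at which it last emitted, and emits one
#' ON (OFF) event per upward (downward) crossing of the contrast `threshold`
#' in log-intensity. Multiple crossings within one inter-frame interval emit
#' multiple events spread uniformly across the interval.
#'
#' `event_converter()` creates the per-pixel state; `convert_step()` ingests
#' one frame and returns the events since the previous frame.
#'
#' @param width,height sensor geometry.
#' @param threshold log-intensity contrast threshold (> 0).
#' @param I_floor additive intensity floor, keeps `log(I + I_floor)` finite.
#' @return `event_converter`: an environment holding converter state.
#' @export
event_converter <- function(width, height, threshold, I_floor = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  st <- new.env(parent = emptyenv())
  st$width <- as.integer(width)
  st$height <- as.integer(height)
  st$threshold <- threshold
  st$I_floor <- I_floor
  st$ref <- NULL        # per-pixel log intensity at last emission
  st$t_prev <- NA_real_ # us
  class(st) <- "event_converter"
  st
}

#' @rdname event_converter
#' @param conv an `event_converter`.
#' @param frame `height x width` matrix of non-negative luminances.
#' @param t_us frame timestamp in microseconds (strictly increasing).
#' @return `convert_step`: an [event_stream()] with events in
#'   `(t_prev, t_us]`.
#' @export
convert_step <- function(conv, frame, t_us) {
  stopifnot(inherits(conv, "event_converter"))
  if (!is.matrix(frame) || nrow(frame) != conv$height ||
      ncol(frame) != conv$width)
    stop("frame geometry mismatch: expected ", conv$height, "x", conv$width)
  if (any(frame < 0)) stop("negative luminance")
  L <- log(frame + conv$I_floor)
  if (is.null(conv$ref)) {
    conv$ref <- L
    conv$t_prev <- t_us
    return(event_stream(width = conv$width, height = conv$height))
  }
  if (t_us <= conv$t_prev) stop("non-increasing frame timestamps")
  d <- L - conv$ref
  k <- floor(abs(d) / conv$threshold)     # number of full threshold crossings
  idx <- which(k > 0)
  if (length(idx) == 0) {
    conv$t_prev <- t_us
    return(event_stream(width = conv$width, height = conv$height))
  }
  kk <- k[idx]
  pol <- as.integer(d[idx] > 0)
  # reference moves by the emitted amount only (residual accumulates)
  conv$ref[idx] <- conv$ref[idx] + sign(d[idx]) * kk * conv$threshold
  rows <- (idx - 1L) %% conv$height       # column-major matrix indexing
  cols <- (idx - 1L) %/% conv$height
  reps <- rep.int(seq_along(idx), kk)
  # j-th of k events in the interval lands at fraction j/(k+1) .. uniform spread
  j <- sequence(kk)
  frac <- j / (kk[reps] + 1)
  tt <- round(conv$t_prev + frac * (t_us - conv$t_prev))
  out <- event_stream(tt, cols[reps], rows[reps], pol[reps],
                      width = conv$width, height = conv$height)
  conv$t_prev <- t_us
  out
}

#' Convert a frame sequence to an event stream
#'
#' Convenience wrapper around [event_converter()]/[convert_step()] for a
#' complete sequence of luminance frames at a fixed 1 ms spacing.
#'
#' @param frames list of `height x width` luminance matrices (>= 2 frames,
#'   identical geometry).
#' @param threshold log-intensity contrast threshold (> 0).
#' @param I_floor additive intensity floor.
#' @param dt_us inter-frame interval in microseconds (default 1000 = 1 kHz).
#' @param t0_us timestamp of the first frame.
#' @return an [event_stream()].
#' @examples
#' f1 <- matrix(1, 4, 4); f2 <- f1; f2[2, 3] <- exp(log(1.05) + 0.3)
#' frames_to_events(list(f1, f2), threshold = 0.25)
#' @export
frames_to_events <- function(frames, threshold, I_floor = 0.05,
                             dt_us = 1000, t0_us = 0) {
  stopifnot(is.list(frames), length(frames) >= 2)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  conv <- event_converter(w, h, threshold, I_floor)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    out[[i]] <- convert_step(conv, frames[[i]], t0_us + (i - 1) * dt_us)
  }
  out <- do.call(rbind, lapply(out, as.data.frame))
  event_stream(out$t, out$x, out$y, out$polarity, width = w, height = h)
}

#' Ornstein-Uhlenbeck camera jitter
#'
#' Mean-reverting stochastic camera micro-movement emulating fixational eye
#' movements: `dx = theta * (mu - x) dt + sigma dW`. Applied to the camera
#' pose before rendering, it sustains event generation from otherwise static
#' scenes. `ou_state()` creates the per-axis state; `ou_step()` advances it by
#' Euler-Maruyama with independent Gaussian increments per axis.
#'
#' @param position numeric vector, one entry per axis (pixels or radians).
#' @param theta attraction rate toward `mu` (1/s, > 0).
#' @param mu central point per axis (recycled).
#' @param sigma drift magnitude (>= 0).
#' @return an `ou_state` list.
#' @examples
#' s <- ou_state(c(0, 0), theta = 4, sigma = 1)
#' s <- ou_step(s, dt = 0.001)
#' @export
ou_state <- function(position = c(0, 0), theta = 4, mu = 0, sigma = 1) {
  stopifnot(theta > 0, sigma >= 0)
  structure(list(position = as.double(position), theta = theta,
                 mu = rep_len(as.double(mu), length(position)),
                 sigma = sigma),
            class = "ou_state")
}

#' @rdname ou_state
#' @param state an `ou_state`.
#' @param dt time step in seconds (> 0).
#' @export
ou_step <- function(state, dt) {
  stopifnot(inherits(state, "ou_state"), dt > 0)
  n <- length(state$position)
  dW <- if (state$sigma > 0) stats::rnorm(n) else numeric(n)
  state$position <- state$position +
    state$theta * (state$mu - state$position) * dt +
    state$sigma * sqrt(dt) * dW
  state
}
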