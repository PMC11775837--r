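#' Population-activity tracker
#'
#' Tracks two exponential moving averages on a 1 ms clock: `S`, the rolling
#' average of the simple-cell population spike count per bin, and `E`, the
#' rolling average of the input event count per bin. Both use the same
#' smoothing `S <- alpha * bin_count + (1 - alpha) * S_prev`.
#'
#' @param alpha smoothing factor in (0, 1], default 0.75.
#' @return an `activity_tracker` list with fields `S`, `E`, `alpha`.
#' @export
activity_tracker <- function(alpha = 0.75) {
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(S = 0, E = 0, alpha = alpha), class = "activity_tracker")
}

#' @rdname activity_tracker
#' @param tr an `activity_tracker`.
#' @param spikes_in_bin simple-cell population spike count in the last 1 ms bin.
#' @param events_in_bin input event count in the same bin.
#' @export
update_activity <- function(tr, spikes_in_bin, events_in_bin) {
  stopifnot(inherits(tr, "activity_tracker"))
  if (spikes_in_bin < 0 || events_in_bin < 0) stop("negative bin counts")
  tr$S <- tr$alpha * spikes_in_bin + (1 - tr$alpha) * tr$S
  tr$E <- tr$alpha * events_in_bin + (1 - tr$alpha) * tr$E
  tr
}

#' Intrinsic reward from coding efficiency
#'
#' The reward is generated by the encoder itself: `R = gamma * (beta - S)/E`,
#' where `S` is the smoothed simple-cell population activity and `E` the
#' smoothed input event rate (per 1 ms bin). Because learned inhibition
#' suppresses activity for frequently seen stimuli, low activity per event -
#' an efficient encoding - yields a high reward. The event-rate normalization
#' makes the reward insensitive to how much input is arriving.
#'
#' When `E` falls below the floor `epsilon` (silent input) the reward is held
#' at 0 and flagged via the `"starved"` attribute.
#'
#' @param tr an [activity_tracker()].
#' @param gamma,beta scale and offset of the reward.
#' @param epsilon event-rate floor below which the reward is undefined.
#' @return scalar reward, with attribute `starved` (logical).
#' @examples
#' tr <- activity_tracker()
#' tr$S <- 80; tr$E <- 10
#' compute_reward(tr)  # 5 * (90 - 80) / 10 = 5
#' @export
compute_reward <- function(tr, gamma = 5, beta = 90, epsilon = 1) {
  stopifnot(inherits(tr, "activity_tracker"))
  if (tr$E < epsilon) {
    return(structure(0, starved = TRUE))
  }
  structure(gamma * (beta - tr$S) / tr$E, starved = FALSE)
}
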