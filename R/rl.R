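#' Population value decoding
#'
#' Decodes the state value from the critic population as an affine function
#' of the mean kernel-estimated firing rate:
#' `V = (nu / N_critic) * sum(rates) / E_norm + V0`. Rates are in the kernel's
#' per-ms units; `V0 < 0` lets a positive-rate code express negative values.
#' With event-rate normalization enabled, `E_norm` is the smoothed input
#' event rate (floored at `epsilon`), which removes the dependence of the
#' value estimate on how much input the network happens to receive.
#'
#' @param rates per-neuron kernel firing-rate estimates (spikes/ms).
#' @param nu scaling factor.
#' @param V0 baseline value at zero rate (mV).
#' @param E_norm event-rate normalizer (1 to disable normalization).
#' @param epsilon floor applied to `E_norm`.
#' @return scalar value estimate (mV).
#' @export
critic_value <- function(rates, nu = 1000, V0 = -20, E_norm = 1,
                         epsilon = 1) {
  E <- max(E_norm, epsilon)
  (nu / length(rates)) * sum(rates) / E + V0
}

#' Smoothed numerical value derivative
#'
#' A second-order numerical differentiation of the value series (sampled at
#' 1 ms): the average of the last `N` central differences, scaled by
#' `eta_actor`: `(eta_actor / N) * sum((V[i+1] - V[i-1]) / 2)`. Averaging over
#' `N` points smooths the variability that event-rate fluctuations induce in
#' the value estimate. A series shorter than `N + 2` yields 0 with the
#' `"short"` attribute set.
#'
#' @param values value series at 1 ms resolution (most recent last).
#' @param N number of central differences to average (>= 1).
#' @param eta_actor scaling factor.
#' @return scalar derivative (mV/ms, scaled by `eta_actor`).
#' @examples
#' value_derivative(seq(0, 10, by = 1), N = 5, eta_actor = 80)  # 80 * slope 1
#' @export
value_derivative <- function(values, N = 10, eta_actor = 80) {
  stopifnot(N >= 1)
  n <- length(values)
  if (n < N + 2) return(structure(0, short = TRUE))
  i <- (n - N):(n - 1)               # centers of the last N central differences
  d <- (values[i + 1] - values[i - 1]) / 2
  structure((eta_actor / N) * sum(d), short = FALSE)
}

#' Continuous-time TD error
#'
#' `delta = v_dot - v / tau_r + r`. In the continuous formulation the reward
#' discount time constant `tau_r` plays the role of the discrete discount
#' factor: at a steady state the self-consistent value is `v = tau_r * r`.
#' A positive error signals an underestimated state, a negative one an
#' overestimated state.
#'
#' @param v_dot value time derivative (per ms).
#' @param v current value estimate.
#' @param r current reward.
#' @param tau_r reward discount time constant (ms).
#' @return scalar TD error.
#' @export
td_error <- function(v_dot, v, r, tau_r = 1) {
  stopifnot(tau_r > 0)
  v_dot - v / tau_r + r
}

#' Eligibility-trace accumulation
#'
#' Per-synapse decaying memory of STDP events for the three-factor rule:
#' the trace decays as `exp(-dt/tau_e)` and is incremented by the STDP amount
#' each time the postsynaptic (critic or actor) neuron spikes. The trace
#' record keeps its own `last_update` so decay can be applied lazily.
#'
#' @param trace list with fields `value` and `last_update` (us), or `NULL`
#'   to create a fresh trace at time `t_now`.
#' @param stdp_increment STDP amount to add after decaying (mV).
#' @param t_now current time (us).
#' @param tau_e eligibility decay time constant (ms).
#' @return updated trace list.
#' @examples
#' tr <- accumulate_eligibility(NULL, 1.0, t_now = 0)
#' tr <- accumulate_eligibility(tr, 0, t_now = 250000)  # decayed by e^-1
#' @export
accumulate_eligibility <- function(trace, stdp_increment, t_now,
                                   tau_e = 250) {
  stopifnot(tau_e > 0)
  if (is.null(trace)) trace <- list(value = 0, last_update = t_now)
  if (t_now < trace$last_update) stop("time must not run backwards")
  dt <- (t_now - trace$last_update) / 1000
  trace$value <- trace$value * exp(-dt / tau_e) + stdp_increment
  trace$last_update <- t_now
  trace
}

#' Three-factor weight update
#'
#' At reward-transmission instants (action selections) each synapse changes
#' by `eta * trace * delta`: the stored STDP history gated by the TD error
#' acting as the neuromodulator. The critic is always updated; for the actor
#' only the group from which the previous action was selected is updated
#' (`gate`). Weights are clamped at zero (the synapses are excitatory).
#'
#' @param weights numeric weight vector (mV).
#' @param traces eligibility-trace values, same length.
#' @param delta TD error.
#' @param eta learning rate.
#' @param gate logical scalar or vector; `FALSE` entries are untouched.
#' @return updated weight vector.
#' @export
apply_three_factor <- function(weights, traces, delta, eta, gate = TRUE) {
  stopifnot(length(weights) == length(traces))
  gate <- rep_len(gate, length(weights))
  w2 <- weights + eta * traces * delta
  w2[w2 < 0] <- 0
  weights[gate] <- w2[gate]
  weights
}

#' Winner-take-all action selection with exploration
#'
#' With probability `lambda_EXP` a uniformly random action is selected;
#' otherwise the action whose actor group accumulated the most spikes since
#' the last selection wins, ties broken uniformly at random.
#'
#' @param counts per-action actor spike counts since the last selection.
#' @param lambda_EXP exploration probability in `[0, 1]`.
#' @return integer action index in `1..length(counts)`, with attribute
#'   `explored` (logical).
#' @export
select_action <- function(counts, lambda_EXP = 0.75) {
  stopifnot(length(counts) >= 1, lambda_EXP >= 0, lambda_EXP <= 1)
  if (lambda_EXP > 0 && stats::runif(1) < lambda_EXP) {
    return(structure(sample.int(length(counts), 1), explored = TRUE))
  }
  best <- which(counts == max(counts))
  a <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
  structure(a, explored = FALSE)
}

#' Exploration/exploitation schedule
#'
#' Creates and decays the learning schedule. Every `Delta_decay` ms of
#' simulated time each scheduled parameter is multiplied by
#' `(1 - eta_decay/100)`; the actor learning rate uses its own smaller decay
#' so the policy keeps learning after the value estimate has converged. The
#' action interval is floored at its minimum.
#'
#' @param lambda_EXP initial exploration probability.
#' @param action_interval initial action-selection interval (ms).
#' @param action_interval_min floor of the action interval (ms).
#' @param eta_critic,eta_actor initial learning rates.
#' @param eta_decay_critic,eta_decay_actor percentage decays per interval.
#' @param Delta_decay interval between decays (ms).
#' @return an `aec_schedule` list.
#' @export
aec_schedule <- function(lambda_EXP = 0.75, action_interval = 250,
                         action_interval_min = 10,
                         eta_critic = 0.2, eta_actor = 0.1,
                         eta_decay_critic = 5, eta_decay_actor = 1.66,
                         Delta_decay = 2000) {
  structure(list(lambda_EXP = lambda_EXP, action_interval = action_interval,
                 action_interval_min = action_interval_min,
                 eta_critic = eta_critic, eta_actor = eta_actor,
                 eta_decay_critic = eta_decay_critic,
                 eta_decay_actor = eta_decay_actor,
                 Delta_decay = Delta_decay),
            class = "aec_schedule")
}

#' @rdname aec_schedule
#' @param s an `aec_schedule`.
#' @export
decay_schedule <- function(s) {
  stopifnot(inherits(s, "aec_schedule"))
  fc <- 1 - s$eta_decay_critic / 100
  fa <- 1 - s$eta_decay_actor / 100
  s$lambda_EXP <- s$lambda_EXP * fc
  s$eta_critic <- s$eta_critic * fc
  s$eta_actor <- s$eta_actor * fa
  s$action_interval <- max(s$action_interval_min, s$action_interval * fc)
  s
}
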