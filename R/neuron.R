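#' Leaky integrate-and-fire neuron state
#'
#' Creates the state record of one LIF neuron with the homeostatic mechanisms
#' used throughout the network: exponential membrane leak (`tau_m`),
#' spike-rate adaptation (a separate adaptive potential `V_SRA` incremented by
#' `eta_SRA` at each spike and decaying with `tau_SRA`), a refractory trace
#' (`eta_RP * exp((t_s - t)/tau_RP)` subtracted from the membrane after each
#' spike), and an adaptive threshold `V_theta`.
#'
#' Between updates the effective membrane potential at time `t` is
#' `V e^(-dt/tau_m) - V_SRA e^(-dt/tau_SRA) - eta_RP e^((t_s - t)/tau_RP)`;
#' a spike is emitted when this reaches `V_theta`, after which `V` is reset to
#' `V_reset` and the homeostatic traces are re-armed.
#'
#' All potentials in mV, time constants in ms, times in microseconds.
#'
#' @param V_thresh initial threshold (mV).
#' @param V_reset reset potential (mV).
#' @param tau_m membrane time constant (ms).
#' @param tau_SRA,eta_SRA spike-rate-adaptation time constant (ms) and per-spike
#'   increment (mV); `eta_SRA = 0` disables the mechanism.
#' @param tau_RP,eta_RP refractory time constant (ms) and amplitude (mV);
#'   `eta_RP = 0` disables it.
#' @param V_min floor applied by inhibitory input (mV).
#' @return a `neuron_state` list with fields `V`, `V_SRA`, `V_theta`, `t_s`,
#'   `t_sm1` (last two spike times, us), `S` (rolling rate, spikes/s),
#'   `last_update` (us) and the parameters.
#' @export
neuron_state <- function(V_thresh = 30, V_reset = -20, tau_m = 18,
                         tau_SRA = 100, eta_SRA = 0.6,
                         tau_RP = 20, eta_RP = 1, V_min = -30) {
  stopifnot(tau_m > 0, tau_SRA > 0, tau_RP > 0)
  structure(list(V = 0, V_SRA = 0, V_theta = V_thresh,
                 t_s = -Inf, t_sm1 = -Inf, S = 0, last_update = 0,
                 V_thresh = V_thresh, V_reset = V_reset, tau_m = tau_m,
                 tau_SRA = tau_SRA, eta_SRA = eta_SRA,
                 tau_RP = tau_RP, eta_RP = eta_RP, V_min = V_min),
            class = "neuron_state")
}

# effective refractory contribution at time t (us), mV
refractory_term <- function(n, t_now) {
  if (!is.finite(n$t_s) || n$eta_RP == 0) return(0)
  n$eta_RP * exp((n$t_s - t_now) / (n$tau_RP * 1000))
}

#' Decay a neuron's potentials to a later time
#'
#' Applies the exponential leak of the membrane potential and of the
#' homeostatic traces from `last_update` to `t_now`. Decay is lazy and
#' time-consistent: decaying by `dt1` then `dt2` equals decaying by
#' `dt1 + dt2`.
#'
#' @param n a [neuron_state()].
#' @param t_now target time in microseconds, `>= n$last_update`.
#' @return the updated `neuron_state`.
#' @export
decay_potential <- function(n, t_now) {
  stopifnot(inherits(n, "neuron_state"))
  if (t_now < n$last_update) stop("time must not run backwards")
  dt <- (t_now - n$last_update) / 1000  # ms
  n$V <- n$V * exp(-dt / n$tau_m)
  n$V_SRA <- n$V_SRA * exp(-dt / n$tau_SRA)
  n$last_update <- t_now
  n
}

# membrane potential as seen by the threshold test: leaked V minus the
# adaptation and refractory terms
effective_potential <- function(n, t_now = n$last_update) {
  n$V - n$V_SRA - refractory_term(n, t_now)
}

#' Deliver a synaptic spike
#'
#' Instantaneous synaptic transmission: after decaying to `t_now`, the
#' membrane potential increases by `w` (excitatory) or decreases by `w`
#' floored at `V_min` (inhibitory).
#'
#' @param n a [neuron_state()].
#' @param w synaptic weight in mV, `>= 0` (the sign is carried by `sign`).
#' @param t_now delivery time (us).
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return the updated `neuron_state`.
#' @export
deliver_spike <- function(n, w, t_now = n$last_update,
                          sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  if (w < 0) stop("weights are non-negative; direction is carried by `sign`")
  n <- decay_potential(n, t_now)
  n$V <- if (sign == "excitatory") n$V + w else max(n$V_min, n$V - w)
  n
}

#' Threshold test and spike emission
#'
#' If the effective membrane potential (leaked potential minus the
#' spike-rate-adaptation and refractory terms) reaches the adaptive threshold
#' `V_theta`, the neuron spikes: the spike time is recorded (shifting
#' `t_s -> t_sm1`), the membrane is reset to `V_reset`, `V_SRA` is incremented
#' by `eta_SRA` and the refractory trace is re-armed.
#'
#' @param n a [neuron_state()].
#' @param t_now test time (us).
#' @return list `(spiked = TRUE/FALSE, state = neuron_state)`.
#' @export
fire_if_threshold <- function(n, t_now = n$last_update) {
  n <- decay_potential(n, t_now)
  if (effective_potential(n, t_now) >= n$V_theta) {
    n$t_sm1 <- n$t_s
    n$t_s <- t_now
    n$V <- n$V_reset
    n$V_SRA <- n$V_SRA + n$eta_SRA
    list(spiked = TRUE, state = n)
  } else {
    list(spiked = FALSE, state = n)
  }
}

#' Static cross-map inhibition
#'
#' When a cell spikes, every cell of a different map at the same
#' receptive-field location has its membrane potential reduced by a fixed
#' `eta_I`, floored at `V_min`. This decorrelates responses across maps and
#' diversifies the learned receptive fields.
#'
#' @param targets list of [neuron_state()] (the spiking neuron excluded).
#' @param eta_I inhibition strength (mV, >= 0).
#' @param t_now delivery time (us).
#' @return list of updated neuron states.
#' @export
apply_static_inhibition <- function(targets, eta_I, t_now = NULL) {
  stopifnot(eta_I >= 0)
  lapply(targets, function(n) {
    if (!is.null(t_now)) n <- decay_potential(n, t_now)
    n$V <- max(n$V_min, n$V - eta_I)
    n
  })
}

#' Threshold adaptation
#'
#' Homeostatic regulation of the firing threshold toward a target rate
#' `S_star`: the threshold moves by `eta_TA * (S - S_star)/S_star` (up when
#' the cell fires above target, down when below), clamped at a positive
#' floor. Driven periodically from the cell's rolling spike rate, it promotes
#' a uniform spike rate across the population.
#'
#' @param n a [neuron_state()].
#' @param eta_TA adaptation step (mV).
#' @param S_star target rate (spikes/s, > 0).
#' @param floor lowest admissible threshold (mV, > 0).
#' @return the updated `neuron_state`.
#' @export
update_threshold <- function(n, eta_TA = 1, S_star = 0.75, floor = 1) {
  stopifnot(S_star > 0, floor > 0)
  n$V_theta <- max(floor, n$V_theta + eta_TA * (n$S - S_star) / S_star)
  n
}

#' Kernel firing-rate estimate
#'
#' Decodes an instantaneous firing rate from a spike train with the
#' double-exponential kernel
#' `kappa(t) = (exp(-t/tau_k) - exp(-t/nu_k)) / (tau_k - nu_k)` for `t >= 0`
#' (0 otherwise). The kernel integrates to exactly 1, so for homogeneous
#' Poisson input the long-run mean estimate equals the true rate in the
#' kernel's time unit (spikes/s here: constants are converted internally).
#'
#' @param spike_times non-decreasing spike times (us).
#' @param t_now evaluation time (us).
#' @param tau_k,nu_k decay and rise constants (ms), `tau_k > nu_k > 0`.
#' @return rate estimate in spikes per second.
#' @examples
#' estimate_rate(c(0, 1000, 2000), t_now = 2000)  # three recent spikes
#' @export
estimate_rate <- function(spike_times, t_now, tau_k = 100, nu_k = 5) {
  stopifnot(tau_k > nu_k, nu_k > 0)
  if (length(spike_times) == 0) return(0)
  if (is.unsorted(spike_times)) stop("spike times must be ordered")
  dt <- (t_now - spike_times) / 1e6           # seconds
  dt <- dt[dt >= 0]
  tk <- tau_k / 1000; nk <- nu_k / 1000       # seconds
  sum((exp(-dt / tk) - exp(-dt / nk)) / (tk - nk))
}
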