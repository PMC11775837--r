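#' Exponential STDP window
#'
#' The timing-dependent weight update used by simple cells and (with its own
#' learning rates) by the plastic inhibitory connections and the
#' critic/actor eligibility traces. Only presynaptic spikes between the
#' neuron's last two postsynaptic spikes contribute
#' (`t_sm1 <= t_i <= t_s`). For each such spike the update is
#' `eta_LTP * exp((t_i - t_s)/tau_LTP) - eta_LTD * exp((t_sm1 - t_i)/tau_LTD)`
#' - potentiation for spikes close before the postsynaptic spike, depression
#' for spikes close after the previous one.
#'
#' @param pre_times presynaptic spike times for one source (us).
#' @param t_s,t_sm1 last and previous postsynaptic spike times (us),
#'   `t_sm1 <= t_s`; use `-Inf` for "never".
#' @param eta_LTP,eta_LTD window heights (mV, >= 0).
#' @param tau_LTP,tau_LTD window widths (ms, > 0).
#' @return total weight change for this source (mV, can be negative).
#' @examples
#' stdp_exponential(pre_times = 10000, t_s = 10000, t_sm1 = 0,
#'                  eta_LTP = 0.00077, eta_LTD = 0.00021)  # coincident: LTP peak
#' @export
stdp_exponential <- function(pre_times, t_s, t_sm1,
                             eta_LTP = 0.00077, eta_LTD = 0.00021,
                             tau_LTP = 7, tau_LTD = 14) {
  stopifnot(t_sm1 <= t_s, eta_LTP >= 0, eta_LTD >= 0,
            tau_LTP > 0, tau_LTD > 0)
  ti <- pre_times[pre_times >= t_sm1 & pre_times <= t_s]
  if (length(ti) == 0) return(0)
  ltp <- eta_LTP * exp((ti - t_s) / (tau_LTP * 1000))
  ltd <- if (is.finite(t_sm1))
    eta_LTD * exp((t_sm1 - ti) / (tau_LTD * 1000)) else 0
  sum(ltp - ltd)
}

#' Step STDP window (complex cells)
#'
#' The pooling layer uses a step-function window centered on the spike times:
#' each presynaptic spike within `tau_LTP` ms of the last postsynaptic spike
#' contributes `+eta_LTP`, and each spike within `tau_LTD` ms of the previous
#' postsynaptic spike contributes `+eta_LTD`. Both parts are positive
#' (weights only grow; normalization provides the only decay); bounds are
#' inclusive.
#'
#' @inheritParams stdp_exponential
#' @param eta_LTP,eta_LTD step heights (mV, >= 0).
#' @param tau_LTP,tau_LTD half-widths of the two windows (ms).
#' @return total weight change for this source (mV, >= 0).
#' @export
stdp_step <- function(pre_times, t_s, t_sm1,
                      eta_LTP = 0.2, eta_LTD = 0.2,
                      tau_LTP = 20, tau_LTD = 20) {
  stopifnot(eta_LTP >= 0, eta_LTD >= 0)
  if (length(pre_times) == 0) return(0)
  n_ltp <- sum(abs(pre_times - t_s) <= tau_LTP * 1000)
  n_ltd <- if (is.finite(t_sm1))
    sum(abs(t_sm1 - pre_times) <= tau_LTD * 1000) else 0
  eta_LTP * n_ltp + eta_LTD * n_ltd
}

#' L1 weight normalization
#'
#' Rescales a weight vector so its L1 norm equals `lambda`, the mechanism
#' that bounds synaptic growth. Negative entries are clamped at zero first
#' (weights are non-negative; the sign of a connection is carried at
#' delivery). The all-zero vector is returned unchanged.
#'
#' @param w numeric weight vector (or matrix, flattened norm).
#' @param lambda target L1 norm (> 0).
#' @return rescaled weights, same shape as `w`.
#' @examples
#' normalize_weights(c(3, 4), lambda = 4)  # c(12/7, 16/7)
#' @export
normalize_weights <- function(w, lambda) {
  stopifnot(lambda > 0)
  w[w < 0] <- 0
  s <- sum(w)
  if (s == 0) return(w)
  w * (lambda / s)
}
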