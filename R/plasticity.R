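#' Parameters for symmetric inhibitory STDP
#'
#' The inhibitory LN->PN synapses follow a symmetric spike-timing-dependent
#' rule with a homeostatic target rate: each presynaptic (LN) spike changes
#' the weight by `eta * (x_post - alpha)` where `x_post` is the exponential
#' trace of recent postsynaptic (PN) spikes and `alpha = 2 * rho_0 *
#' tau_istdp` is the depression factor fixing the target postsynaptic rate
#' `rho_0`; each postsynaptic spike potentiates by `eta * x_pre`.
#'
#' @param eta Learning rate (weight units per pairing).
#' @param tau_istdp Trace time constant (ms).
#' @param rho_0 Target postsynaptic rate (Hz).
#' @param w_min,w_max Weight bounds.
#' @return List of class `istdp_params`; `alpha` is computed, not settable.
#' @export
istdp_params <- function(eta = 0.005, tau_istdp = 20, rho_0 = 15,
                         w_min = 0, w_max = 25) {
  stopifnot(eta > 0, tau_istdp > 0, rho_0 >= 0, w_max > w_min)
  structure(list(eta = eta, tau_istdp = tau_istdp, rho_0 = rho_0,
                 alpha = 2 * (rho_0 / 1000) * tau_istdp,
                 w_min = w_min, w_max = w_max),
            class = "istdp_params")
}

#' Parameters for the asymmetric STDP kernel and octopamine modulation
#'
#' @param A_plus,A_minus Kernel magnitudes for causal (potentiating) and
#'   anti-causal (depressing) pairings; `A_minus` is negative and the
#'   defaults are balanced (`A_plus * tau_plus = -A_minus * tau_minus`), so
#'   uncorrelated pre/post activity produces no net drift and only causal
#'   structure moves weights.
#' @param tau_plus,tau_minus Kernel time constants (ms).
#' @param d Octopamine concentration parameter (dimensionless amplification
#'   just after reward is `1 + d`).
#' @param tau_d Eligibility time constant (ms).
#' @param w_min,w_max Weight bounds.
#' @return List of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.0035, A_minus = -0.0035, tau_plus = 20,
                        tau_minus = 20, d = 20, tau_d = 400,
                        w_min = 0, w_max = 1) {
  stopifnot(tau_plus > 0, tau_minus > 0, tau_d > 0, w_max > w_min)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, d = d, tau_d = tau_d,
                 w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' iSTDP update on a presynaptic (LN) spike
#'
#' @param weight Current weight.
#' @param x_post Postsynaptic trace value at the presynaptic event.
#' @param params [istdp_params()].
#' @return Updated weight, clipped to bounds.
#' @export
istdp_on_pre <- function(weight, x_post, params = istdp_params()) {
  pmin(pmax(weight + params$eta * (x_post - params$alpha), params$w_min),
       params$w_max)
}

#' iSTDP update on a postsynaptic (PN) spike
#'
#' Potentiation-only: the change `eta * x_pre` is never negative.
#'
#' @param weight Current weight.
#' @param x_pre Presynaptic trace value at the postsynaptic event.
#' @param params [istdp_params()].
#' @return Updated weight, clipped to bounds.
#' @export
istdp_on_post <- function(weight, x_pre, params = istdp_params()) {
  pmin(pmax(weight + params$eta * x_pre, params$w_min), params$w_max)
}

#' Asymmetric STDP kernel
#'
#' Weight-change magnitude for a pre/post spike pair separated by
#' `delta_t = t_post - t_pre` (ms): `A_plus * exp(-delta_t / tau_plus)` for
#' causal pairs (`delta_t > 0`), `A_minus * exp(delta_t / tau_minus)` for
#' anti-causal pairs; exactly coincident spikes contribute zero by
#' convention.
#'
#' @param delta_t Spike-time difference(s) in ms.
#' @param params [stdp_params()].
#' @return Numeric vector of weight changes.
#' @export
stdp_kernel <- function(delta_t, params = stdp_params()) {
  ifelse(delta_t > 0, params$A_plus * exp(-delta_t / params$tau_plus),
         ifelse(delta_t < 0, params$A_minus * exp(delta_t / params$tau_minus),
                0))
}

#' Octopamine eligibility factor
#'
#' Multiplicative gate applied to STDP updates: 1 before the reward, and
#' `1 + d * exp(-(t - t_reward) / tau_d)` after it (a decaying eligibility
#' window). `strict = TRUE` uses the growing exponent
#' `1 + d * exp((t - t_reward) / tau_d)` instead, which diverges with time
#' after the reward; it is provided for comparison only.
#'
#' @param t Time (ms).
#' @param t_reward Reward time (ms); `Inf` means no reward.
#' @param params [stdp_params()].
#' @param strict Use the unbounded growing-exponent form.
#' @return Scalar (or vector) factor, >= 1.
#' @export
eligibility_factor <- function(t, t_reward, params = stdp_params(),
                               strict = FALSE) {
  ifelse(t < t_reward, 1,
         1 + params$d * exp((if (strict) 1 else -1) *
                              (t - t_reward) / params$tau_d))
}

#' Reward-modulated STDP weight update
#'
#' Applies `f_d(t) * STDP(delta_t)` to a weight and clips to capacity
#' bounds. Without a reward (`t_reward = Inf`) this reduces to plain STDP.
#'
#' @param weight Current weight.
#' @param delta_t Spike-time difference `t_post - t_pre` (ms).
#' @param t Time of the update (ms).
#' @param t_reward Reward time (ms); `Inf` for unrewarded.
#' @param params [stdp_params()].
#' @param strict See [eligibility_factor()].
#' @return Updated weight within bounds.
#' @export
modulated_update <- function(weight, delta_t, t, t_reward = Inf,
                             params = stdp_params(), strict = FALSE) {
  dw <- eligibility_factor(t, t_reward, params, strict) *
    stdp_kernel(delta_t, params)
  pmin(pmax(weight + dw, params$w_min), params$w_max)
}

#' All-pairs brute-force iSTDP weight change (oracle)
#'
#' Direct evaluation of the symmetric iSTDP rule by summing over every
#' pre/post spike pair: each pre spike contributes
#' `eta * (sum_post-before exp(-dt/tau) - alpha)` and each post spike
#' contributes `eta * sum_pre-before exp(-dt/tau)`. Pairs are restricted to
#' strictly earlier partner spikes; no weight bounds are applied. Quadratic
#' in spike count; intended as an independent check of the event-driven
#' trace implementation on short trains.
#'
#' @param pre_times,post_times Spike times (ms) of the pre (LN) and post
#'   (PN) neuron.
#' @param params [istdp_params()].
#' @return Total weight change (scalar).
#' @export
istdp_all_pairs <- function(pre_times, post_times,
                            params = istdp_params()) {
  tau <- params$tau_istdp
  d_pre <- vapply(pre_times, function(tp) {
    sum(exp(-(tp - post_times[post_times < tp]) / tau)) - params$alpha
  }, numeric(1))
  d_post <- vapply(post_times, function(tp) {
    sum(exp(-(tp - pre_times[pre_times < tp]) / tau))
  }, numeric(1))
  params$eta * (sum(d_pre) + sum(d_post))
}

#' Event-driven iSTDP weight change via exponential traces
#'
#' The implementation used inside the network simulator: spikes are
#' processed in time order; each neuron carries an exponentially decaying
#' trace that is read by the partner's events (spikes strictly earlier than
#' the event) and incremented afterwards. Equivalent to
#' [istdp_all_pairs()] up to floating-point rounding.
#'
#' @inheritParams istdp_all_pairs
#' @return Total weight change (scalar).
#' @export
istdp_event_driven <- function(pre_times, post_times,
                               params = istdp_params()) {
  tau <- params$tau_istdp
  times <- sort(unique(c(pre_times, post_times)))
  x_pre <- 0; x_post <- 0
  t_last <- if (length(times)) times[1] else 0
  dw <- 0
  for (t in times) {
    dec <- exp(-(t - t_last) / tau)
    x_pre <- x_pre * dec
    x_post <- x_post * dec
    t_last <- t
    n_pre <- sum(pre_times == t)
    n_post <- sum(post_times == t)
    # reads use traces of strictly earlier spikes only
    if (n_pre > 0) dw <- dw + n_pre * params$eta * (x_post - params$alpha)
    if (n_post > 0) dw <- dw + n_post * params$eta * x_pre
    x_pre <- x_pre + n_pre
    x_post <- x_post + n_post
  }
  dw
}
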