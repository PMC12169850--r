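#' Static sigmoidal response function
#'
#' The rate-prediction nonlinearity used inside every plasticity rule:
#' `phi(v) = phi0 / (1 + exp(g * beta0 * (g * theta0 - v)))`. With default
#' parameters the midpoint sits at `v = g * theta0 = 3` where the rate is
#' `phi0 / 2 = 25` Hz, and the slope is `g * beta0 = 15`.
#'
#' @param v potential (dimensionless), any length.
#' @param params a [neuron_params()] object.
#' @return rates in Hz, same length as `v`, in `(0, phi0)`.
#' @examples
#' p <- neuron_params()
#' static_sigmoid(p$g * p$theta0, p)  # 25 Hz at the midpoint
#' @export
static_sigmoid <- function(v, params = neuron_params()) {
  params$phi0 / (1 + exp(params$g * params$beta0 *
                           (params$g * params$theta0 - v)))
}

#' Dynamic (homeostatically regulated) response function
#'
#' The instantaneous firing rate of a network neuron. The homeostatic
#' variable `h` shifts the sigmoid threshold to `g * theta0 * h`, so that a
#' neuron whose membrane potential sits at its recent maximum (where
#' `h = u / (g * theta0)`, see [update_h()]) fires at `phi0 / 2`. A large `h`
#' (a history of large potentials) therefore lowers excitability, and the
#' slow decay of `h` after input removal restores it, which is what lets the
#' network re-ignite spontaneous replay. At `h = 1` the function coincides
#' with [static_sigmoid()].
#'
#' `h` values below `h_floor` are clamped (with a warning) rather than
#' accepted, so the threshold never collapses to zero.
#'
#' @param u membrane potential(s), dimensionless.
#' @param h homeostatic variable(s); scalar or same length as `u`.
#' @param params a [neuron_params()] object.
#' @return rates in Hz, in `(0, phi0)`, monotone increasing in `u`.
#' @examples
#' p <- neuron_params()
#' dynamic_sigmoid(p$g * 2 * p$theta0, h = 2, p)  # 25 Hz at the midpoint
#' dynamic_sigmoid(0.5, h = 0.1, p)               # recovered excitability
#' @export
dynamic_sigmoid <- function(u, h, params = neuron_params()) {
  if (any(h < params$h_floor)) {
    warning("h below h_floor clamped in dynamic_sigmoid")
    h <- pmax(h, params$h_floor)
  }
  params$phi0 / (1 + exp(params$g * params$beta0 *
                           (params$g * params$theta0 * h - u)))
}

#' Update the homeostatic variable
#'
#' `h` is a two-timescale envelope of the membrane potential, measured in
#' units of the resting threshold `g * theta0`: when the normalized
#' potential `u / (g * theta0)` exceeds `h`, the variable relaxes upward
#' toward it with the rise time constant `tau_r`; otherwise it decays
#' exponentially with the (much longer) time constant `tau_h`. It is
#' clamped below at `h_floor`. Between upward excursions of the potential
#' `h` is strictly decreasing, so it acts as a slowly forgetting envelope
#' of the potential's driven excursions over roughly the last `tau_h`
#' milliseconds.
#'
#' Normalizing by the resting threshold makes the learned operating point
#' self-consistent: when the potential repeatedly reaches
#' `u = g * theta0` (the static-sigmoid midpoint), `h` settles at 1 and the
#' dynamic response function equals the static one. The finite rise time
#' makes the set-point reflect the typical driven potential across
#' stimulus presentations rather than the momentary peak within one; see
#' the methods vignette for why this (and a threshold-borne, not
#' gain-borne, homeostasis) is required for the network to fire and
#' re-ignite at all.
#'
#' @param h current homeostatic value(s), `>= h_floor`.
#' @param u current membrane potential(s).
#' @param params a [neuron_params()] object.
#' @return updated `h`, same length as `u`.
#' @examples
#' p <- neuron_params()
#' update_h(2, 1, p)  # decays: 2 * exp(-1e-4)
#' update_h(1, 6, p)  # rises toward 6 / (g * theta0) = 2 with tau_r
#' @export
update_h <- function(h, u, params = neuron_params()) {
  stopifnot(all(h >= params$h_floor))
  un <- u / (params$g * params$theta0)
  rise <- 1 - exp(-params$dt / params$tau_r)
  out <- ifelse(h > un, h * exp(-params$dt / params$tau_h),
                h + (un - h) * rise)
  pmax(out, params$h_floor)
}

#' Exponentially decaying presynaptic trace with unit spike jumps
#'
#' One Euler step of the synaptic trace driven by the kernel
#' `eps(s) = exp(-s / tau)` for `s >= 0`: the trace decays by
#' `exp(-dt / tau)` and a spike in the current step adds `eps(0) = 1`
#' immediately. Summing this update over a spike train reproduces the
#' convolution of the train with the kernel exactly (at the step times).
#'
#' @param trace current trace value(s), non-negative.
#' @param spiked logical (or 0/1) spike indicator(s), recycled against
#'   `trace`.
#' @param dt time step (ms).
#' @param tau trace time constant (ms).
#' @return updated non-negative trace(s).
#' @examples
#' decay_and_jump_trace(1, FALSE, dt = 15, tau = 15)  # exp(-1)
#' decay_and_jump_trace(0, TRUE, dt = 1, tau = 15)    # 1
#' @export
decay_and_jump_trace <- function(trace, spiked, dt, tau) {
  if (dt <= 0 || tau <= 0) stop("dt and tau must be positive")
  stopifnot(all(trace >= 0))
  trace * exp(-dt / tau) + as.numeric(spiked)
}
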