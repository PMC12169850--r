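#' Neuron and learning-rule constants
#'
#' Collects the fixed constants of the spiking-neuron model and its plasticity
#' rules. Defaults are the values used throughout the study conditions this
#' package reproduces: a 1-ms Euler step, a 15-ms membrane/trace time
#' constant, a 10-s homeostatic time constant, a 50-Hz rate ceiling, and a
#' learning rate of 1e-4.
#'
#' The instantaneous firing rate is a sigmoid of the membrane potential with
#' slope `g * beta0` and midpoint `g * theta0 * h`, where `h` is the
#' homeostatic variable tracking the running maximum of the membrane
#' potential (in units of the resting threshold `g * theta0`); see
#' [dynamic_sigmoid()] and [update_h()].
#'
#' @param dt integration time step (ms).
#' @param tau membrane/presynaptic-trace time constant (ms).
#' @param tau_h homeostatic decay time constant (ms); must exceed `tau`.
#' @param tau_r homeostatic rise time constant (ms): how quickly `h`
#'   relaxes upward toward the current (threshold-normalized) membrane
#'   potential. Slow relative to one stimulus presentation, so the
#'   excitability set-point reflects the typical driven potential across
#'   presentations rather than the within-presentation peak; fast relative
#'   to `tau_h`.
#' @param phi0 maximum instantaneous firing rate (Hz).
#' @param g dimensionless scale of the response function.
#' @param beta0 base gain of the sigmoid.
#' @param theta0 base threshold of the sigmoid.
#' @param eta learning rate of all plasticity rules.
#' @param h_floor lower clamp for the homeostatic variable; guards the
#'   response function against a vanishing threshold. Default runs never
#'   reach it (clamping is reported by the simulation engine).
#'
#' @return An object of class `neuron_params` (a validated list).
#' @examples
#' p <- neuron_params()
#' p$phi0 * p$dt / 1000  # maximal per-step spike probability (0.05)
#' @export
neuron_params <- function(dt = 1, tau = 15, tau_h = 10000, tau_r = 1000,
                          phi0 = 50, g = 3, beta0 = 5, theta0 = 1,
                          eta = 1e-4, h_floor = 1e-2) {
  p <- list(dt = dt, tau = tau, tau_h = tau_h, tau_r = tau_r, phi0 = phi0,
            g = g, beta0 = beta0, theta0 = theta0, eta = eta,
            h_floor = h_floor)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  if (dt <= 0) stop("dt must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (tau_h <= tau) stop("tau_h must exceed tau")
  if (tau_r <= 0 || tau_r >= tau_h) stop("tau_r must lie in (0, tau_h)")
  if (phi0 <= 0) stop("phi0 must be positive")
  if (eta <= 0) stop("eta must be positive")
  if (h_floor <= 0) stop("h_floor must be positive")
  if (phi0 * dt / 1000 > 1)
    stop("phi0 * dt / 1000 exceeds 1: per-step spike probability is not valid")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Neuron/learning parameters:\n")
  cat(sprintf("  dt = %g ms, tau = %g ms, tau_h = %g ms, tau_r = %g ms\n",
              x$dt, x$tau, x$tau_h, x$tau_r))
  cat(sprintf("  phi0 = %g Hz, g = %g, beta0 = %g, theta0 = %g\n",
              x$phi0, x$g, x$beta0, x$theta0))
  cat(sprintf("  eta = %g, h_floor = %g\n", x$eta, x$h_floor))
  invisible(x)
}

as_params_list <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  unclass(p)
}
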