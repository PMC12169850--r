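#' Shared prediction-error factor of all plasticity rules
#'
#' `E(f, v) = phi0^-1 * (1 - phi(v)/phi0) * (f - phi(v))`, where `phi` is
#' [static_sigmoid()]. It vanishes when the prediction is exact
#' (`f = phi(v)`), carries the sign of `f - phi(v)`, and is suppressed when
#' the prediction saturates (`phi(v) -> phi0`). Every weight update in the
#' package is `eta * E(f, v_class) * presynaptic_trace`.
#'
#' @param f postsynaptic instantaneous rate(s), Hz.
#' @param v prediction potential(s) of one connection class.
#' @param params a [neuron_params()] object.
#' @return dimensionless error(s).
#' @examples
#' p <- neuron_params()
#' error_term(50, 3, p)  # (1/50) * (1 - 0.5) * (50 - 25) = 0.25
#' @export
error_term <- function(f, v, params = neuron_params()) {
  stopifnot(all(f >= 0), all(f <= params$phi0))
  phi <- static_sigmoid(v, params)
  (1 / params$phi0) * (1 - phi / params$phi0) * (f - phi)
}

#' Plasticity rules of the mixed-sign (nDL) model
#'
#' Online gradient rules minimizing, per connection class, the mismatch
#' between the neuron's firing rate and the class's rate prediction:
#' `dW[i,j] = eta * E(f_i, vW_i) * x_j` (signed, no truncation), and
#' analogously for `M` against `vM` with trace `y`. The inhibitory-only
#' matrix `G` uses the same form against `vG` but is clamped at zero from
#' below after every update.
#'
#' @param W,M,G weight matrices.
#' @param f postsynaptic rates (length N).
#' @param v_W,v_M,v_G prediction potentials of the class being updated.
#' @param x,y presynaptic traces (afferent / recurrent).
#' @param eta learning rate.
#' @param params a [neuron_params()] object.
#' @return the updated matrix.
#' @name ndl_rules
NULL

#' @rdname ndl_rules
#' @export
update_W <- function(W, f, v_W, x, eta = params$eta,
                     params = neuron_params()) {
  W + outer(eta * error_term(f, v_W, params), x)
}

#' @rdname ndl_rules
#' @export
update_M_nDL <- function(M, f, v_M, y, eta = params$eta,
                         params = neuron_params()) {
  M + outer(eta * error_term(f, v_M, params), y)
}

#' @rdname ndl_rules
#' @export
update_G_nDL <- function(G, f, v_G, y, eta = params$eta,
                         params = neuron_params()) {
  pmax(G + outer(eta * error_term(f, v_G, params), y), 0)
}

#' Plasticity step of the sign-constrained (signed) model
#'
#' `M_exc` and `M_inh` share the joint prediction `v = vM_exc - vM_inh` and
#' move in opposite directions (`+eta*E*y` and `-eta*E*y`), so a positive
#' error strengthens excitation and weakens this inhibition simultaneously.
#' `G` learns against its own prediction as in the nDL model, and `W`
#' against the afferent prediction. All recurrent matrices are truncated to
#' non-negative values after the step; updates respect the fixed
#' pair-to-matrix assignment masks.
#'
#' @param weights a `"signed"` [network_weights()] object.
#' @param f postsynaptic rates.
#' @param x,y presynaptic traces used for the potentials.
#' @param eta learning rate.
#' @param params a [neuron_params()] object.
#' @param plastic character subset of `c("W", "M", "G")` to update.
#' @return the updated `network_weights`.
#' @export
update_signed <- function(weights, f, x, y, eta = params$eta,
                          params = neuron_params(),
                          plastic = c("W", "M", "G")) {
  stopifnot(weights$kind == "signed")
  v <- membrane_potential(weights, x, y)$v
  if ("W" %in% plastic)
    weights$W <- update_W(weights$W, f, v$W, x, eta, params)
  if ("M" %in% plastic) {
    dJ <- outer(eta * error_term(f, v$M, params), y)
    weights$M_exc <- pmax(weights$M_exc + dJ * weights$mask_exc, 0)
    weights$M_inh <- pmax(weights$M_inh - dJ * weights$mask_inh, 0)
  }
  if ("G" %in% plastic) {
    dG <- outer(eta * error_term(f, v$G, params), y)
    weights$G <- pmax(weights$G + dG * weights$mask_g, 0)
  }
  weights
}

#' Plasticity step of the Dale's-law (DL) model
#'
#' Per postsynaptic population X: the afferent rule updates `W_X` against
#' `vW`; the path-2 joint prediction `vM2 = M_XE yE - G2_XI yI` drives
#' `M_XE` (`+eta*E*yE`) and `G2_XI` (`-eta*E*yI`) in opposite directions;
#' the path-1 prediction `vM1 = G1_XI yI` drives `G1_XI` alone
#' (`+eta*E*yI`). Recurrent matrices are truncated to non-negative values;
#' `W_X` stays signed.
#'
#' @param weights a `"DL"` [network_weights()] object.
#' @param f `list(E =, I =)` postsynaptic rates.
#' @param x afferent traces.
#' @param y `list(E =, I =)` recurrent traces.
#' @param eta learning rate.
#' @param params a [neuron_params()] object.
#' @param plastic character subset of `c("W", "M", "G")`: `"M"` gates the
#'   path-2 pair, `"G"` gates path 1.
#' @return the updated `network_weights`.
#' @export
update_DL <- function(weights, f, x, y, eta = params$eta,
                      params = neuron_params(),
                      plastic = c("W", "M", "G")) {
  stopifnot(weights$kind == "DL")
  v <- membrane_potential(weights, x, y)$v
  for (X in c("E", "I")) {
    if ("W" %in% plastic) {
      nm <- paste0("W_", X)
      weights[[nm]] <- update_W(weights[[nm]], f[[X]], v[[X]]$W, x, eta,
                                params)
    }
    if ("M" %in% plastic) {
      e2 <- eta * error_term(f[[X]], v[[X]]$M2, params)
      nm_m <- paste0("M_", X, "E"); nm_g2 <- paste0("G2_", X, "I")
      weights[[nm_m]] <- pmax(weights[[nm_m]] + outer(e2, y$E), 0)
      weights[[nm_g2]] <- pmax(weights[[nm_g2]] - outer(e2, y$I), 0)
    }
    if ("G" %in% plastic) {
      e1 <- eta * error_term(f[[X]], v[[X]]$M1, params)
      nm_g1 <- paste0("G1_", X, "I")
      weights[[nm_g1]] <- pmax(weights[[nm_g1]] + outer(e1, y$I), 0)
    }
  }
  weights
}

#' Plasticity gating configuration
#'
#' Describes which weight matrices learn and when. `schedule` is a list of
#' intervals `list(t_start, t_end, enabled)` (ms, half-open
#' `[t_start, t_end)`); outside every interval the default `enabled` set
#' applies. The canonical experiment schedule is: everything plastic during
#' learning, everything off for the 20-s recovery after input removal, and
#' a selectable set afterwards.
#'
#' @param eta learning rate.
#' @param enabled named logical over the matrix classes, default all on.
#' @param schedule list of gating intervals (must not overlap).
#' @return an object of class `plasticity_config`.
#' @examples
#' cfg <- plasticity_config(schedule = list(
#'   list(t_start = 3e5, t_end = 3.2e5, enabled = character(0))))
#' apply_gating(cfg, 3.1e5)  # recovery window: nothing learns
#' @export
plasticity_config <- function(eta = 1e-4,
                              enabled = c(W = TRUE, M = TRUE, G = TRUE),
                              schedule = list()) {
  stopifnot(is.logical(enabled), !is.null(names(enabled)))
  for (iv in schedule) {
    if (!all(c("t_start", "t_end", "enabled") %in% names(iv)) ||
        iv$t_start >= iv$t_end)
      stop("each gating interval needs t_start < t_end and an enabled set")
  }
  if (length(schedule) > 1) {
    ss <- order(vapply(schedule, `[[`, 0, "t_start"))
    sorted <- schedule[ss]
    for (i in seq_len(length(sorted) - 1)) {
      if (sorted[[i]]$t_end > sorted[[i + 1]]$t_start)
        stop("gating intervals overlap")
    }
  }
  structure(list(eta = eta, enabled = enabled, schedule = schedule),
            class = "plasticity_config")
}

#' @rdname plasticity_config
#' @param config a `plasticity_config`.
#' @param t time (ms).
#' @return character vector of matrix classes plastic at time `t`.
#' @export
apply_gating <- function(config, t) {
  stopifnot(inherits(config, "plasticity_config"))
  for (iv in config$schedule) {
    if (t >= iv$t_start && t < iv$t_end) return(iv$enabled)
  }
  names(config$enabled)[config$enabled]
}
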