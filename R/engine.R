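#' Run one simulation phase
#'
#' Advances a network through a rate program with a fixed plasticity
#' setting, using the compiled Euler loop (or a pure-R reference loop built
#' from the exported single-step operations; both consume the RNG stream in
#' the same order and produce bit-identical trajectories). The weights and
#' state are updated in place in the returned network; recordings
#' (per-neuron spike counts, optional binned counts, prediction-error
#' traces, and raster) describe the phase just simulated.
#'
#' @param net a list with elements `weights` ([network_weights()]),
#'   `state` ([network_state()]) and `params` ([neuron_params()]), e.g. a
#'   fitted [replaynet()] object.
#' @param program a `rate_program` (use [blank_program()] for spontaneous
#'   phases).
#' @param plastic character subset of `c("W", "M", "G")`; empty means all
#'   plasticity off.
#' @param fixed_h freeze the homeostatic variable (ablation).
#' @param bin_ms if `> 0`, also return spike counts binned at this width.
#' @param trace_ms if `> 0`, record population means (prediction errors per
#'   connection class, `h`, rate) every `trace_ms`.
#' @param raster if `TRUE`, return the spike raster (capped at
#'   `max_raster` events).
#' @param max_raster raster cap.
#' @param engine `"cpp"` (default) or `"r"` (reference loop; nDL/signed
#'   only, meant for short runs).
#' @return `list(net =, rec =)`: the advanced network and a
#'   `phase_recording` with elements `counts`, `rates` (Hz), `duration_ms`,
#'   `bins`, `traces`, `raster` (for `"DL"`, counts/bins/raster are lists
#'   over populations `E` and `I`).
#' @export
run_phase <- function(net, program, plastic = c("W", "M", "G"),
                      fixed_h = FALSE, bin_ms = 0, trace_ms = 0,
                      raster = FALSE, max_raster = 2e6,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(program, "rate_program"))
  w <- net$weights; st <- net$state; p <- net$params
  stopifnot(nrow(program$rates) == w$n_inputs)
  prob <- program$rates * p$dt / 1000
  stopifnot(all(prob <= 1))
  dt <- p$dt
  bin_steps <- if (bin_ms > 0) max(1L, round(bin_ms / dt)) else 0L
  trace_every <- if (trace_ms > 0) max(1L, round(trace_ms / dt)) else 0L
  par <- as_params_list(p)
  dur <- program$n_steps * dt

  if (engine == "r") {
    out <- run_phase_r(w, st, prob, program$program, p, plastic, fixed_h)
  } else if (w$kind == "nDL") {
    use_mask <- !is.null(w$w_mask)
    out <- sim_ndl_cpp(w$W, w$M, w$G, st$x, st$y, st$h, st$t, prob,
                       program$program, par, "W" %in% plastic,
                       "M" %in% plastic, "G" %in% plastic, fixed_h,
                       if (use_mask) w$w_mask else matrix(0, 0, 0), use_mask,
                       bin_steps, trace_every, raster, max_raster)
  } else if (w$kind == "signed") {
    out <- sim_signed_cpp(w$W, w$M_exc, w$M_inh, w$G, w$mask_exc, w$mask_inh,
                          w$mask_g, st$x, st$y, st$h, st$t, prob,
                          program$program, par, "W" %in% plastic,
                          "M" %in% plastic, "G" %in% plastic, fixed_h,
                          bin_steps, trace_every, raster, max_raster)
  } else {
    out <- sim_dl_cpp(w$W_E, w$W_I, w$M_EE, w$M_IE, w$G1_EI, w$G2_EI,
                      w$G1_II, w$G2_II, st$x, st$y$E, st$y$I, st$h$E,
                      st$h$I, st$t, prob, program$program, par,
                      "W" %in% plastic, "M" %in% plastic, "G" %in% plastic,
                      fixed_h, bin_steps, trace_every, raster, max_raster)
  }

  if (w$kind == "DL") {
    for (nm in c("W_E", "W_I", "M_EE", "M_IE", "G1_EI", "G2_EI", "G1_II",
                 "G2_II")) w[[nm]] <- out[[nm]]
    st$x <- drop(out$x)
    st$y <- list(E = drop(out$y_E), I = drop(out$y_I))
    st$h <- list(E = drop(out$h_E), I = drop(out$h_I))
    st$t <- out$t
    counts <- list(E = drop(out$counts_E), I = drop(out$counts_I))
    rates <- lapply(counts, function(cc) cc / dur * 1000)
    bins <- if (bin_steps > 0 && engine == "cpp")
      list(E = out$bins_E, I = out$bins_I) else NULL
    ras <- if (raster && engine == "cpp")
      list(E = raster_df(out$raster_E), I = raster_df(out$raster_I)) else NULL
  } else {
    for (nm in weight_matrix_names(w)) w[[nm]] <- out[[nm]]
    st$x <- drop(out$x); st$y <- drop(out$y); st$h <- drop(out$h)
    st$t <- out$t
    counts <- drop(out$counts)
    rates <- counts / dur * 1000
    bins <- if (bin_steps > 0) out$bins else NULL
    ras <- if (raster && !is.null(out$raster)) raster_df(out$raster) else NULL
  }
  traces <- if (trace_every > 0 && !is.null(out$traces) &&
                nrow(out$traces) > 0) {
    stats::setNames(as.data.frame(out$traces),
                    c("t_ms", "err_W", "err_M", "err_G", "h_mean", "f_mean"))
  } else NULL

  net$weights <- w
  net$state <- st
  rec <- structure(list(counts = counts, rates = rates, duration_ms = dur,
                        bin_ms = bin_ms, bins = bins, traces = traces,
                        raster = ras, plastic = plastic,
                        h_clamps = if (is.null(out$h_clamps)) NA_real_
                                   else out$h_clamps),
                   class = "phase_recording")
  list(net = net, rec = rec)
}

raster_df <- function(r) {
  data.frame(neuron = as.integer(r$neuron), time_ms = as.numeric(r$time_ms))
}

# Pure-R reference loop. Mirrors the compiled engine step for step,
# including the RNG draw order, so short runs can be compared bit for bit.
run_phase_r <- function(weights, state, prob, program, params, plastic,
                        fixed_h) {
  K <- weights$n_inputs
  steps <- length(program)
  counts <- if (weights$kind == "DL") {
    list(E = numeric(weights$n_neurons), I = numeric(weights$n_inh))
  } else numeric(weights$n_neurons)
  for (s in seq_len(steps)) {
    in_spikes <- as.integer(stats::runif(K) < prob[, program[s]])
    y_pre <- state$y
    state <- step_network(state, weights, in_spikes, params,
                          mode = "evoked", fixed_h = fixed_h)
    v <- attr(state, "v")
    if (length(plastic)) {
      if (weights$kind == "nDL") {
        if ("W" %in% plastic) {
          dW <- outer(params$eta * error_term(state$f, v$W, params), state$x)
          if (!is.null(weights$w_mask)) dW <- dW * weights$w_mask
          weights$W <- weights$W + dW
        }
        if ("M" %in% plastic)
          weights$M <- update_M_nDL(weights$M, state$f, v$M, y_pre,
                                    params$eta, params)
        if ("G" %in% plastic)
          weights$G <- update_G_nDL(weights$G, state$f, v$G, y_pre,
                                    params$eta, params)
      } else if (weights$kind == "signed") {
        weights <- update_signed(weights, state$f, state$x, y_pre,
                                 params$eta, params, plastic)
      } else {
        weights <- update_DL(weights, state$f, state$x, y_pre, params$eta,
                             params, plastic)
      }
    }
    if (weights$kind == "DL") {
      counts$E <- counts$E + state$spikes$E
      counts$I <- counts$I + state$spikes$I
    } else counts <- counts + state$spikes
  }
  out <- weights[weight_matrix_names(weights)]
  if (weights$kind == "DL") {
    c(out, list(x = state$x, y_E = state$y$E, y_I = state$y$I,
                h_E = state$h$E, h_I = state$h$I, t = state$t,
                counts_E = counts$E, counts_I = counts$I,
                bins = NULL, traces = NULL, raster = NULL))
  } else {
    c(out, list(x = state$x, y = state$y, h = state$h, t = state$t,
                counts = counts, bins = NULL, traces = NULL, raster = NULL))
  }
}
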