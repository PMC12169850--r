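#' Fit a predictive-plasticity replay network
#'
#' Trains a recurrent network of Poisson spiking neurons on a stochastic
#' stimulation protocol with the predictive plasticity rule on every
#' synapse, then removes the input, lets the network recover with
#' plasticity off, and identifies the self-organized cell assemblies with
#' evoked probes. The returned object holds the learned weights and the
#' post-recovery network state, so [simulate.replaynet()] can generate the
#' spontaneous replay activity whose assembly statistics encode the
#' training probabilities, and [predict.replaynet()] can generate evoked
#' responses.
#'
#' The training pipeline is: (1) `learn_ms` of stimulation with all
#' selected plasticity rules active; (2) `recover_ms` of input-free
#' recovery with all plasticity off, during which the homeostatic variable
#' decays and excitability recovers; (3) evoked probes (plasticity off,
#' `probe_presentations` per stimulus) used by [assign_assemblies()].
#'
#' @param stimulus a [pattern_spec()], [coherence_spec()] or
#'   [conditioned_spec()] describing the training protocol. For a
#'   conditioned spec the afferent matrix is automatically masked so that
#'   input groups 1-2 project only to subnetwork A (the first half of the
#'   neurons) and groups 3-4 only to subnetwork B; recurrent connectivity
#'   stays all-to-all.
#' @param n_neurons network size N (excitatory pool for `kind = "DL"`).
#' @param kind model variant: `"nDL"` (mixed-sign recurrent weights),
#'   `"signed"` (sign-constrained synapses) or `"DL"` (separate
#'   excitatory/inhibitory populations).
#' @param params a [neuron_params()] object.
#' @param learn_ms learning-phase duration (ms).
#' @param recover_ms plasticity-off recovery after input removal (ms).
#' @param probe_presentations evoked presentations per stimulus used for
#'   assembly identification.
#' @param selectivity_threshold threshold for [assign_assemblies()].
#' @param plastic which weight classes learn during the learning phase.
#' @param fixed_h freeze the homeostatic variable at its initial value
#'   (ablation).
#' @param n_inh inhibitory pool size (`"DL"` only).
#' @param trace_ms sampling interval of the training log.
#' @param seed optional seed (`set.seed()` is called if given).
#' @return An object of class `replaynet` with components `weights`,
#'   `state` (post-recovery), `params`, `stimulus`, `schedule_freqs`
#'   (empirical presentation frequencies), `assignment`, `evoked_rates`,
#'   `training_log`, `fixed_h` and `call`.
#' @seealso [simulate.replaynet()], [predict.replaynet()],
#'   [run_experiment()] for the config-driven wrapper.
#' @examples
#' \donttest{
#' set.seed(1)
#' fit <- replaynet(pattern_spec(2, group_size = 20), n_neurons = 30,
#'                  learn_ms = 20000)
#' summary(fit)
#' }
#' @export
replaynet <- function(stimulus, n_neurons = 100,
                      kind = c("nDL", "signed", "DL"),
                      params = neuron_params(), learn_ms = 3e5,
                      recover_ms = 2e4, probe_presentations = 20,
                      selectivity_threshold = 0.3,
                      plastic = c("W", "M", "G"), fixed_h = FALSE,
                      n_inh = n_neurons, trace_ms = 1000, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(stimulus, "pattern_spec"), learn_ms > 0,
            recover_ms >= 0)
  if (!is.null(seed)) set.seed(seed)

  w_mask <- if (inherits(stimulus, "conditioned_spec"))
    conditioned_w_mask(n_neurons, stimulus) else NULL
  weights <- network_weights(n_neurons, stimulus$n_inputs, kind,
                             n_inh = n_inh, w_mask = w_mask)
  net <- list(weights = weights, state = network_state(weights, params),
              params = params)

  sched <- build_schedule(stimulus, learn_ms)
  res <- run_phase(net, schedule_to_rates(sched, params$dt),
                   plastic = plastic, fixed_h = fixed_h,
                   trace_ms = trace_ms)
  net <- res$net
  training_log <- res$rec$traces

  if (recover_ms > 0) {
    net <- run_phase(net, blank_program(stimulus$n_inputs, recover_ms,
                                        params$dt),
                     plastic = character(0), fixed_h = fixed_h)$net
  }
  post_recovery <- net$state

  probed <- probe_evoked_rates(net, stimulus, probe_presentations, fixed_h)
  assignment <- assign_assemblies(probed, selectivity_threshold)

  structure(list(weights = net$weights, state = post_recovery,
                 params = params, kind = kind, stimulus = stimulus,
                 schedule_freqs = empirical_frequencies(sched),
                 assignment = assignment, evoked_rates = probed,
                 training_log = training_log, fixed_h = fixed_h,
                 learn_ms = learn_ms, recover_ms = recover_ms,
                 call = match.call()),
            class = "replaynet")
}

# afferent mask of the two-subnetwork conditioned protocol: groups 1-2 drive
# the first half of the neurons, groups 3-4 the second half
conditioned_w_mask <- function(n_neurons, spec) {
  stopifnot(inherits(spec, "conditioned_spec"))
  half <- floor(n_neurons / 2)
  mask <- matrix(0, n_neurons, spec$n_inputs)
  a_inputs <- spec$membership[, 1] | spec$membership[, 2]
  mask[seq_len(half), a_inputs] <- 1
  mask[(half + 1):n_neurons, !a_inputs] <- 1
  mask
}

# trial-averaged evoked rates per stimulus (plasticity off); state copies,
# the incoming network is not advanced
probe_evoked_rates <- function(net, stimulus, presentations, fixed_h) {
  n <- stimulus$n_patterns
  N <- net$weights$n_neurons
  if (net$weights$kind == "DL") N <- N  # probes read the excitatory pool
  cyc <- stimulus$duration_ms + stimulus$interval_ms
  out <- matrix(0, N, n)
  for (j in seq_len(n)) {
    pspec <- stimulus
    pspec$probabilities <- as.numeric(seq_len(n) == j)
    class(pspec) <- setdiff(class(pspec), "conditioned_spec")
    psched <- build_schedule(pspec, presentations * cyc)
    pres <- run_phase(net, schedule_to_rates(psched, net$params$dt),
                      plastic = character(0), fixed_h = fixed_h)
    r <- pres$rec$rates
    out[, j] <- if (is.list(r)) r$E else r
  }
  out
}

#' @export
print.replaynet <- function(x, ...) {
  cat(sprintf("Predictive-plasticity replay network (%s)\n", x$kind))
  cat(sprintf("  N = %d neurons, K = %d inputs, %d stimuli\n",
              x$weights$n_neurons, x$weights$n_inputs,
              x$stimulus$n_patterns))
  cat(sprintf("  trained %.0f s; empirical stimulus frequencies: %s\n",
              x$learn_ms / 1000,
              paste(sprintf("%.2f", x$schedule_freqs), collapse = ", ")))
  sz <- assembly_sizes(x$assignment)
  cat("  assemblies:", paste(sz, collapse = ", "),
      " unassigned:", sum(is.na(x$assignment)), "\n")
  invisible(x)
}

#' @export
summary.replaynet <- function(object, ...) {
  x <- object
  sz <- assembly_sizes(x$assignment)
  tl <- x$training_log
  err <- if (!is.null(tl)) {
    k <- max(1, nrow(tl) - 9)
    c(start = mean(tl$err_W[seq_len(min(10, nrow(tl)))]),
      end = mean(tl$err_W[k:nrow(tl)]))
  } else c(start = NA, end = NA)
  out <- list(kind = x$kind, n_neurons = x$weights$n_neurons,
              n_inputs = x$weights$n_inputs,
              frequencies = x$schedule_freqs, sizes = sz,
              unassigned = sum(is.na(x$assignment)),
              err_W = err,
              h_mean = mean(unlist(x$state$h)))
  class(out) <- "summary.replaynet"
  out
}

#' @export
print.summary.replaynet <- function(x, ...) {
  cat(sprintf("%s model, N = %d, K = %d\n", x$kind, x$n_neurons,
              x$n_inputs))
  cat("stimulus frequencies:",
      paste(sprintf("%.3f", x$frequencies), collapse = ", "), "\n")
  cat("assembly sizes:", paste(x$sizes, collapse = ", "),
      "(unassigned:", x$unassigned, ")\n")
  cat(sprintf("afferent prediction error |f - phi(vW)|: %.3f (start) -> %.3f (end)\n",
              x$err_W["start"], x$err_W["end"]))
  cat(sprintf("post-recovery mean h: %.3f\n", x$h_mean))
  invisible(x)
}

#' Extract the learned synaptic matrices
#'
#' @param object a fitted [replaynet()].
#' @param ... unused.
#' @return named list of weight matrices (see [network_weights()]).
#' @export
coef.replaynet <- function(object, ...) {
  object$weights[weight_matrix_names(object$weights)]
}

#' Prediction-error traces of the training run
#'
#' The residuals of the fit are the population-mean absolute prediction
#' errors `|f - phi(v_class)|` per connection class, sampled over training
#' time.
#'
#' @param object a fitted [replaynet()].
#' @param ... unused.
#' @return data frame with columns `t_ms`, `err_W`, `err_M`, `err_G`.
#' @export
residuals.replaynet <- function(object, ...) {
  prediction_error_trace(object)
}

#' Simulate activity of a trained replay network
#'
#' Runs the trained network forward from its post-recovery state, either
#' input-free (`mode = "spontaneous"`, the replay condition) or driven by
#' a stimulus (`mode = "evoked"`). The fitted object is not modified; each
#' of the `nsim` repetitions starts from the same stored state with a
#' fresh stretch of the RNG stream.
#'
#' @param object a fitted [replaynet()].
#' @param nsim number of repetitions.
#' @param seed optional seed.
#' @param duration_ms epoch length (ms).
#' @param mode `"spontaneous"` or `"evoked"`.
#' @param stimulus for evoked mode: a stimulus id (probing that pattern)
#'   or, for coherence fits, a coherence value in `[-0.5, 0.5]`.
#' @param plastic plasticity during the epoch (default off, the metric
#'   condition).
#' @param bin_ms width of binned spike counts (0 to disable).
#' @param raster return the spike raster.
#' @param fixed_h freeze the homeostatic variable at its stored
#'   (post-recovery) value for the epoch — the sampling-accuracy
#'   ablation. Defaults to the fit's own setting.
#' @param ... unused.
#' @return for `nsim = 1` a `replay_sim` object: a `phase_recording` plus
#'   `pops` (per-assembly population rates, Hz) and `assignment`;
#'   otherwise a list of them.
#' @export
simulate.replaynet <- function(object, nsim = 1, seed = NULL,
                               duration_ms = 1e5,
                               mode = c("spontaneous", "evoked"),
                               stimulus = NULL, plastic = character(0),
                               bin_ms = 20, raster = FALSE,
                               fixed_h = object$fixed_h, ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  K <- object$weights$n_inputs
  program <- if (mode == "spontaneous") {
    blank_program(K, duration_ms, object$params$dt)
  } else {
    evoked_program(object, stimulus, duration_ms)
  }
  one <- function() {
    net <- list(weights = object$weights, state = object$state,
                params = object$params)
    res <- run_phase(net, program, plastic = plastic,
                     fixed_h = fixed_h, bin_ms = bin_ms,
                     raster = raster)
    rec <- res$rec
    r <- if (is.list(rec$rates)) rec$rates$E else rec$rates
    rec$pops <- population_activity(r, object$assignment)
    rec$assignment <- object$assignment
    rec$mode <- mode
    class(rec) <- c("replay_sim", class(rec))
    rec
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

evoked_program <- function(object, stimulus, duration_ms) {
  spec <- object$stimulus
  K <- spec$n_inputs
  if (inherits(spec, "coherence_spec") && is.numeric(stimulus) &&
      length(stimulus) == 1 && stimulus >= -0.5 && stimulus <= 0.5 &&
      !(stimulus %in% seq_len(spec$n_patterns) &&
        isTRUE(all.equal(stimulus, round(stimulus))))) {
    cr <- coherence_rates(stimulus, spec$r_max)
    rates <- numeric(K)
    rates[spec$membership[, 1]] <- cr[["R"]]
    rates[spec$membership[, 2]] <- cr[["L"]]
    constant_program(rates, K, duration_ms, object$params$dt)
  } else {
    id <- as.integer(stimulus)
    stopifnot(length(id) == 1, id >= 1, id <= spec$n_patterns)
    rates <- rep(spec$background_rate, K)
    rates[spec$membership[, id]] <- spec$pattern_rate
    constant_program(rates, K, duration_ms, object$params$dt)
  }
}

#' @export
print.replay_sim <- function(x, ...) {
  r <- if (is.list(x$rates)) x$rates$E else x$rates
  cat(sprintf("%s epoch, %.0f s: mean rate %.2f Hz\n", x$mode,
              x$duration_ms / 1000, mean(r)))
  cat("  assembly population rates (Hz):",
      paste(sprintf("%.1f", x$pops), collapse = ", "), "\n")
  invisible(x)
}

#' Psychometric predictions of a trained decision network
#'
#' For a network trained on the motion-coherence protocol, probes the
#' model with test stimuli across a coherence grid (plasticity off) and
#' returns the percentage of rightward choices, defined as the evoked
#' activity ratio of the R-encoding assembly times 100. For
#' pattern-trained fits, returns trial-averaged evoked per-assembly
#' population rates for the probed stimuli instead.
#'
#' @param object a fitted [replaynet()].
#' @param coherence numeric vector of test coherences (coherence fits).
#' @param stimulus integer vector of stimulus ids (pattern fits).
#' @param n_trials probe repetitions per condition.
#' @param trial_ms probe stimulus duration (ms).
#' @param seed optional seed.
#' @param ... unused.
#' @return coherence fits: data frame `coh, choices_to_right_pct, sd`;
#'   pattern fits: matrix of per-assembly population rates (rows =
#'   probed stimuli).
#' @export
predict.replaynet <- function(object, coherence = NULL, stimulus = NULL,
                              n_trials = 20, trial_ms = 1000, seed = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  asg <- object$assignment
  if (!is.null(coherence)) {
    stopifnot(inherits(object$stimulus, "coherence_spec"))
    rows <- lapply(coherence, function(coh) {
      ars <- vapply(seq_len(n_trials), function(i) {
        sim <- simulate(object, duration_ms = trial_ms, mode = "evoked",
                        stimulus = coh, bin_ms = 0)
        activity_ratio_AR(sim$pops[1], sim$pops[2])
      }, 0)
      data.frame(coh = coh,
                 choices_to_right_pct = choices_to_right(mean(ars)),
                 sd = choices_to_right(stats::sd(ars)))
    })
    do.call(rbind, rows)
  } else {
    ids <- if (is.null(stimulus)) seq_len(object$stimulus$n_patterns)
           else as.integer(stimulus)
    out <- t(vapply(ids, function(id) {
      pops <- matrix(0, n_trials, attr(asg, "n_assemblies"))
      for (i in seq_len(n_trials)) {
        sim <- simulate(object, duration_ms = trial_ms, mode = "evoked",
                        stimulus = id, bin_ms = 0)
        pops[i, ] <- sim$pops
      }
      colMeans(pops)
    }, numeric(attr(asg, "n_assemblies"))))
    rownames(out) <- paste0("stimulus_", ids)
    out
  }
}

#' Plot a fitted replay network
#'
#' `type = "training"` shows the prediction-error traces and the
#' population-mean homeostatic variable against training time;
#' `type = "weights"` shows the recurrent matrix with neurons sorted by
#' assembly; `type = "raster"` simulates a short spontaneous epoch and
#' plots the spike raster sorted by assembly.
#'
#' @param x a fitted [replaynet()].
#' @param type plot type.
#' @param duration_ms raster epoch length.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.replaynet <- function(x, type = c("training", "weights", "raster"),
                           duration_ms = 1e4, ...) {
  type <- match.arg(type)
  if (type == "training") {
    tl <- x$training_log
    if (is.null(tl)) stop("no training log recorded")
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    graphics::matplot(tl$t_ms / 1000, tl[, c("err_W", "err_M", "err_G")],
                      type = "l", lty = 1, xlab = "time (s)",
                      ylab = "|f - phi(v)| (Hz)", ...)
    graphics::legend("topright", c("W", "M", "G"), col = 1:3, lty = 1,
                     bty = "n")
    graphics::plot(tl$t_ms / 1000, tl$h_mean, type = "l",
                   xlab = "time (s)", ylab = "mean h")
  } else if (type == "weights") {
    M <- if (x$kind == "nDL") x$weights$M
         else if (x$kind == "signed") x$weights$M_exc - x$weights$M_inh
         else x$weights$M_EE
    ord <- order(x$assignment, na.last = TRUE)
    graphics::image(M[ord, ord], useRaster = TRUE,
                    xlab = "presynaptic (sorted)",
                    ylab = "postsynaptic (sorted)", ...)
  } else {
    sim <- simulate(x, duration_ms = duration_ms, raster = TRUE,
                    bin_ms = 0)
    ras <- if (is.list(sim$raster) && !is.data.frame(sim$raster))
      sim$raster$E else sim$raster
    ord <- order(x$assignment, na.last = TRUE)
    pos <- match(ras$neuron, ord)
    graphics::plot(ras$time_ms / 1000, pos, pch = ".", cex = 2,
                   xlab = "time (s)", ylab = "neuron (sorted)", ...)
  }
  invisible(x)
}
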