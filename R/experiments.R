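#' Experiment configuration
#'
#' Bundles everything that defines one simulation experiment: the model
#' variant and size, the stimulation protocol, phase durations
#' (learn, input-free recovery, spontaneous analysis epoch), plasticity
#' settings per phase, ablation switches and the seed. Configurations
#' round-trip through JSON via [write_config()] / [read_config()].
#'
#' Defaults are the scaled study conditions used throughout the package:
#' N = 100 neurons, 300-s learning, 20-s recovery, 100-s spontaneous
#' epoch.
#'
#' @param stimulus a [pattern_spec()], [coherence_spec()] or
#'   [conditioned_spec()].
#' @param kind model variant.
#' @param n_neurons,n_inh network sizes.
#' @param params a [neuron_params()] object.
#' @param learn_ms,recover_ms,spont_ms phase durations (ms).
#' @param probe_presentations evoked presentations per stimulus for
#'   assembly identification.
#' @param selectivity_threshold see [assign_assemblies()].
#' @param plastic weight classes plastic during learning.
#' @param spont_plastic weight classes plastic during the spontaneous
#'   epoch (empty = frozen weights, the default metric condition).
#' @param fixed_h freeze the homeostatic variable (ablation).
#' @param remove_between_assembly_excitation zero the positive recurrent
#'   entries that cross assemblies before the spontaneous epoch
#'   (probe-time ablation).
#' @param bin_ms bin width for spontaneous spike-count recording.
#' @param seed RNG seed for the whole experiment.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(stimulus, kind = "nDL", n_neurons = 100,
                              n_inh = n_neurons, params = neuron_params(),
                              learn_ms = 3e5, recover_ms = 2e4,
                              spont_ms = 1e5, probe_presentations = 20,
                              selectivity_threshold = 0.3,
                              plastic = c("W", "M", "G"),
                              spont_plastic = character(0),
                              fixed_h = FALSE,
                              remove_between_assembly_excitation = FALSE,
                              bin_ms = 20, seed = 1) {
  stopifnot(inherits(stimulus, "pattern_spec"), learn_ms > 0,
            recover_ms >= 0, spont_ms > 0)
  structure(list(stimulus = stimulus, kind = kind, n_neurons = n_neurons,
                 n_inh = n_inh, params = params, learn_ms = learn_ms,
                 recover_ms = recover_ms, spont_ms = spont_ms,
                 probe_presentations = probe_presentations,
                 selectivity_threshold = selectivity_threshold,
                 plastic = plastic, spont_plastic = spont_plastic,
                 fixed_h = fixed_h,
                 remove_between_assembly_excitation =
                   remove_between_assembly_excitation,
                 bin_ms = bin_ms, seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config: %s, N = %d, %d stimuli, seed %d\n",
              x$kind, x$n_neurons, x$stimulus$n_patterns, x$seed))
  cat(sprintf("  phases: learn %.0f s, recover %.0f s, spontaneous %.0f s\n",
              x$learn_ms / 1000, x$recover_ms / 1000, x$spont_ms / 1000))
  invisible(x)
}

#' Run a full experiment: learn, recover, probe, spontaneous, metrics
#'
#' Executes the standard protocol described by an [experiment_config()]:
#' trains a [replaynet()], identifies assemblies, applies any probe-time
#' ablation, simulates the spontaneous epoch, and computes the replay
#' metrics. Deterministic given the config seed.
#'
#' @param config an [experiment_config()].
#' @return a list of class `experiment_result`: `fit` (the trained
#'   [replaynet()]), `spont` (the spontaneous `replay_sim`), `report`
#'   (a `metrics_report`), and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  fit <- replaynet(config$stimulus, n_neurons = config$n_neurons,
                   kind = config$kind, params = config$params,
                   learn_ms = config$learn_ms,
                   recover_ms = config$recover_ms,
                   probe_presentations = config$probe_presentations,
                   selectivity_threshold = config$selectivity_threshold,
                   plastic = config$plastic, fixed_h = config$fixed_h,
                   n_inh = config$n_inh)
  if (config$remove_between_assembly_excitation)
    fit <- remove_between_assembly_excitation(fit)
  spont <- simulate(fit, duration_ms = config$spont_ms,
                    plastic = config$spont_plastic,
                    bin_ms = config$bin_ms)
  report <- metrics_report(fit, spont)
  structure(list(fit = fit, spont = spont, report = report,
                 config = config),
            class = "experiment_result")
}

#' Zero the positive between-assembly recurrent weights
#'
#' Probe-time ablation: excitatory (positive) entries of the recurrent
#' matrix whose pre- and postsynaptic neurons belong to different
#' assemblies are set to zero. Spontaneous replay statistics survive this
#' ablation because replay is driven by within-assembly recurrence.
#'
#' @param fit a fitted [replaynet()] (nDL).
#' @return the modified fit.
#' @export
remove_between_assembly_excitation <- function(fit) {
  stopifnot(fit$kind == "nDL")
  asg <- as.integer(fit$assignment)
  M <- fit$weights$M
  cross <- outer(asg, asg, "!=")
  cross[is.na(cross)] <- TRUE
  fit$weights$M <- ifelse(cross & M > 0, 0, M)
  fit
}

#' Replay metrics of a spontaneous epoch
#'
#' Collects the quantitative measures reported on a trained network and
#' its spontaneous activity: assembly sizes, per-assembly mean single-cell
#' rates and population rates, the firing-rate / assembly-size /
#' assembly-activity ratios of the target assembly, normalized
#' within-assembly excitatory incoming weights, and the within- vs
#' between-assembly correlation contrast of binned spontaneous counts.
#'
#' @param fit a fitted [replaynet()].
#' @param spont a spontaneous `replay_sim` from [simulate.replaynet()].
#' @param target target assembly id for the ratio metrics.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(fit, spont, target = 1) {
  asg <- fit$assignment
  rates <- if (is.list(spont$rates)) spont$rates$E else spont$rates
  n <- attr(asg, "n_assemblies")
  sizes <- assembly_sizes(asg)
  pops <- population_activity(rates, asg)
  mean_rates <- ifelse(sizes > 0, pops / sizes, NA_real_)
  M <- switch(fit$kind, nDL = fit$weights$M,
              signed = fit$weights$M_exc - fit$weights$M_inh,
              DL = fit$weights$M_EE)
  corr <- if (!is.null(spont$bins)) {
    b <- if (is.list(spont$bins)) spont$bins$E else spont$bins
    if (ncol(b) >= 100)
      assembly_correlation_contrast(pairwise_correlations(b), asg)
    else c(within = NA_real_, between = NA_real_)
  } else c(within = NA_real_, between = NA_real_)
  structure(list(
    sizes = sizes, pops = pops, mean_rates = mean_rates,
    unassigned = sum(is.na(asg)),
    firing_rate_ratio = firing_rate_ratio(rates, asg, target),
    assembly_size_ratio = assembly_size_ratio(rates, asg, target),
    assembly_activity_ratio = assembly_activity_ratio(rates, asg, target),
    normalized_incoming_weights =
      normalized_excitatory_incoming_weights(M, asg),
    correlation = corr, target = target),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Replay metrics (target assembly", x$target, ")\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "),
      " unassigned:", x$unassigned, "\n")
  cat("  population rates (Hz):",
      paste(sprintf("%.1f", x$pops), collapse = ", "), "\n")
  cat(sprintf("  ratios: firing-rate %.2f, size %.2f, activity %.2f\n",
              x$firing_rate_ratio, x$assembly_size_ratio,
              x$assembly_activity_ratio))
  cat("  normalized incoming weights:",
      paste(sprintf("%.3f", x$normalized_incoming_weights),
            collapse = ", "), "\n")
  cat(sprintf("  correlations: within %.3f, between %.3f\n",
              x$correlation["within"], x$correlation["between"]))
  invisible(x)
}

#' Sweep the occurrence-probability ratio of stimulus 1
#'
#' Repeats the standard experiment while stimulus 1 is presented `ratio`
#' times as often as each of the other patterns, with independent seeds
#' per trial, and reports the three ratio metrics (mean and SD across
#' trials).
#'
#' @param ratios numeric vector of probability ratios (>= 1 recommended).
#' @param n_patterns number of stimuli.
#' @param n_trials independent trials per ratio.
#' @param base_config an [experiment_config()] whose stimulus/seed are
#'   replaced per run; `NULL` builds the default scaled config.
#' @param seed master seed from which per-trial seeds are drawn.
#' @return data frame with one row per (ratio, trial) plus aggregate
#'   means/SDs in attribute `"summary"`.
#' @export
run_probability_sweep <- function(ratios, n_patterns = 3, n_trials = 5,
                                  base_config = NULL, seed = 1) {
  stopifnot(length(ratios) >= 1, n_patterns >= 2)
  set.seed(seed)
  trial_seeds <- matrix(sample.int(.Machine$integer.max,
                                   length(ratios) * n_trials),
                        nrow = length(ratios))
  rows <- list()
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    probs <- c(r, rep(1, n_patterns - 1))
    probs <- probs / sum(probs)
    for (tr in seq_len(n_trials)) {
      cfg <- if (is.null(base_config)) {
        experiment_config(pattern_spec(n_patterns, probabilities = probs),
                          seed = trial_seeds[i, tr])
      } else {
        bc <- base_config
        bc$stimulus <- pattern_spec(
          n_patterns, group_size = base_config$stimulus$group_size,
          probabilities = probs)
        bc$seed <- trial_seeds[i, tr]
        bc
      }
      res <- run_experiment(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        ratio = r, trial = tr,
        firing_rate_ratio = res$report$firing_rate_ratio,
        size_ratio = res$report$assembly_size_ratio,
        activity_ratio = res$report$assembly_activity_ratio)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(
    out[c("firing_rate_ratio", "size_ratio", "activity_ratio")],
    by = list(ratio = out$ratio),
    function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v)))
  attr(out, "summary") <- agg
  out
}

#' Train and test the perceptual decision-making model
#'
#' Trains the network on fully coherent rightward/leftward motion stimuli
#' presented with the protocol probabilities (`c(0.5, 0.5)` unbiased or
#' `c(0.8, 0.2)` biased), then measures the spontaneous activity ratio AR
#' of the R-encoding assembly over a post-recovery input-free epoch and,
#' optionally, the psychometric curve over a grid of test coherences.
#'
#' @param protocol training presentation probabilities `c(R, L)`.
#' @param coh_grid optional test coherence grid for the psychometric
#'   curve (`NULL` skips the probes).
#' @param n_probe_trials probe repetitions per coherence.
#' @param n_neurons network size.
#' @param learn_ms,recover_ms,spont_ms phase durations (ms).
#' @param params a [neuron_params()] object.
#' @param seed RNG seed.
#' @return list of class `decision_result`: `fit`, `AR` (spontaneous
#'   activity ratio), `spont_pops`, and `psychometric` (data frame or
#'   `NULL`).
#' @export
run_decision_task <- function(protocol = c(0.5, 0.5), coh_grid = NULL,
                              n_probe_trials = 20, n_neurons = 100,
                              learn_ms = 3e5, recover_ms = 2e4,
                              spont_ms = 1e5, params = neuron_params(),
                              seed = 1) {
  stopifnot(length(protocol) == 2, abs(sum(protocol) - 1) < 1e-8)
  set.seed(seed)
  spec <- coherence_spec(probabilities = protocol)
  fit <- replaynet(spec, n_neurons = n_neurons, params = params,
                   learn_ms = learn_ms, recover_ms = recover_ms)
  spont <- simulate(fit, duration_ms = spont_ms)
  ar <- activity_ratio_AR(spont$pops[1], spont$pops[2])
  psy <- if (!is.null(coh_grid))
    predict(fit, coherence = coh_grid, n_trials = n_probe_trials) else NULL
  structure(list(fit = fit, AR = ar, spont_pops = spont$pops,
                 psychometric = psy, protocol = protocol),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf("Decision task (%.0f:%.0f protocol): spontaneous AR = %.3f\n",
              100 * x$protocol[1], 100 * x$protocol[2], x$AR))
  if (!is.null(x$psychometric)) print(x$psychometric)
  invisible(x)
}

#' Conditioned-prior experiment on two coupled subnetworks
#'
#' Trains the two-subnetwork model on the conditioned protocol (S1/S2 to
#' subnetwork A, S3/S4 to subnetwork B with conditional probabilities),
#' then probes with S1 or S2 alone (S3/S4 off) and reports the fraction
#' of subnetwork-B activity carried by the S4-encoding assembly. After
#' learning, that fraction approximates the trained conditional
#' probability P(S4 | A-stimulus).
#'
#' @param cond_table 2 x 2 conditional probability table (rows S1/S2).
#' @param n_neurons network size (split into two equal subnetworks).
#' @param learn_ms,recover_ms phase durations (ms).
#' @param n_probe_trials probe repetitions per A-stimulus.
#' @param trial_ms probe duration (ms).
#' @param params a [neuron_params()] object.
#' @param seed RNG seed.
#' @return list of class `conditioned_result` with the fitted model and
#'   `fractions`: per A-stimulus, the measured S4 activity fraction next
#'   to the trained conditional probability.
#' @export
run_conditioned_prior <- function(cond_table = matrix(c(1/3, 2/3, 2/3, 1/3),
                                                      2, 2, byrow = TRUE),
                                  n_neurons = 100, learn_ms = 3e5,
                                  recover_ms = 2e4, n_probe_trials = 20,
                                  trial_ms = 1000,
                                  params = neuron_params(), seed = 1) {
  set.seed(seed)
  spec <- conditioned_spec(cond_table = cond_table)
  fit <- replaynet(spec, n_neurons = n_neurons, params = params,
                   learn_ms = learn_ms, recover_ms = recover_ms)
  fractions <- vapply(1:2, function(a_id) {
    fr <- vapply(seq_len(n_probe_trials), function(i) {
      sim <- simulate(fit, duration_ms = trial_ms, mode = "evoked",
                      stimulus = a_id, bin_ms = 0)
      p3 <- sim$pops[3]; p4 <- sim$pops[4]
      if (p3 + p4 == 0) NA_real_ else p4 / (p3 + p4)
    }, 0)
    mean(fr, na.rm = TRUE)
  }, 0)
  structure(list(fit = fit, cond_table = cond_table,
                 fractions = data.frame(
                   a_stimulus = c("S1", "S2"),
                   s4_fraction = fractions,
                   trained_p_s4 = cond_table[, 2])),
            class = "conditioned_result")
}

#' @export
print.conditioned_result <- function(x, ...) {
  cat("Conditioned-prior experiment\n")
  print(x$fractions)
  invisible(x)
}

#' Write or read an experiment configuration as JSON
#'
#' @param config an [experiment_config()].
#' @param file JSON path.
#' @return `write_config()` the path, invisibly; `read_config()` the
#'   restored `experiment_config`.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- config$stimulus
  stim <- list(
    type = class(spec)[1], n_patterns = spec$n_patterns,
    group_size = spec$group_size,
    overlap_fraction = spec$overlap_fraction,
    pattern_rate = spec$pattern_rate,
    background_rate = spec$background_rate,
    duration_ms = spec$duration_ms, interval_ms = spec$interval_ms,
    probabilities = spec$probabilities, order = spec$order)
  if (!is.null(spec$cond_table)) {
    stim$cond_table <- spec$cond_table
    stim$a_probabilities <- spec$a_probabilities
  }
  body <- config[setdiff(names(config), c("stimulus", "params"))]
  jsonlite::write_json(list(stimulus = stim,
                            params = as_params_list(config$params),
                            config = body),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  s <- j$stimulus
  stimulus <- switch(s$type,
    coherence_spec = coherence_spec(
      group_size = s$group_size, r_max = s$pattern_rate,
      background_rate = s$background_rate, duration_ms = s$duration_ms,
      interval_ms = s$interval_ms, probabilities = s$probabilities),
    conditioned_spec = conditioned_spec(
      cond_table = matrix(unlist(s$cond_table), 2, 2),
      a_probabilities = s$a_probabilities, group_size = s$group_size,
      pattern_rate = s$pattern_rate,
      background_rate = s$background_rate,
      duration_ms = s$duration_ms, interval_ms = s$interval_ms),
    pattern_spec(s$n_patterns, group_size = s$group_size,
                 overlap_fraction = s$overlap_fraction,
                 pattern_rate = s$pattern_rate,
                 background_rate = s$background_rate,
                 duration_ms = s$duration_ms,
                 interval_ms = s$interval_ms,
                 probabilities = s$probabilities, order = s$order))
  params <- do.call(neuron_params, as.list(j$params))
  cfg <- j$config
  experiment_config(stimulus, kind = cfg$kind,
                    n_neurons = cfg$n_neurons, n_inh = cfg$n_inh,
                    params = params, learn_ms = cfg$learn_ms,
                    recover_ms = cfg$recover_ms, spont_ms = cfg$spont_ms,
                    probe_presentations = cfg$probe_presentations,
                    selectivity_threshold = cfg$selectivity_threshold,
                    plastic = unlist(cfg$plastic),
                    spont_plastic = if (length(cfg$spont_plastic))
                      unlist(cfg$spont_plastic) else character(0),
                    fixed_h = cfg$fixed_h,
                    remove_between_assembly_excitation =
                      cfg$remove_between_assembly_excitation,
                    bin_ms = cfg$bin_ms, seed = cfg$seed)
}
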