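#' Probabilistic pattern stimulation protocol
#'
#' Defines the synthetic afferent input used for training: `n_patterns`
#' groups of `group_size` input neurons; a pattern presentation drives its
#' group at `pattern_rate` Hz for `duration_ms`, separated by
#' `interval_ms`-long gaps; outside a pattern's members (and during gaps)
#' every input neuron fires irregularly at `background_rate` Hz. With no
#' overlap the number of input neurons is `K = group_size * n_patterns`;
#' with `overlap_fraction > 0`, consecutive groups share that fraction of
#' their members.
#'
#' @param n_patterns number of stimulus patterns.
#' @param group_size input neurons per pattern.
#' @param overlap_fraction fraction of members shared between consecutive
#'   groups, in `[0, 1)`.
#' @param pattern_rate firing rate (Hz) of a presented pattern's members.
#' @param background_rate baseline firing rate (Hz) of all input neurons.
#' @param duration_ms pattern length (ms).
#' @param interval_ms gap between consecutive patterns (ms).
#' @param probabilities occurrence probability per pattern (sums to 1).
#' @param order `"random"` (i.i.d. draws from `probabilities`) or
#'   `"fixed_sequence"` (patterns cycle 1, 2, ..., n, 1, ...).
#' @return an object of class `pattern_spec`; its `membership` element is
#'   the K x n_patterns logical matrix of group memberships.
#' @examples
#' spec <- pattern_spec(2, probabilities = c(0.3, 0.7))
#' spec$n_inputs
#' @export
pattern_spec <- function(n_patterns, group_size = 100, overlap_fraction = 0,
                         pattern_rate = 50, background_rate = 2,
                         duration_ms = 100, interval_ms = 100,
                         probabilities = rep(1 / n_patterns, n_patterns),
                         order = c("random", "fixed_sequence")) {
  order <- match.arg(order)
  n <- as.integer(n_patterns)
  stopifnot(n >= 1, group_size >= 1, overlap_fraction >= 0,
            overlap_fraction < 1, pattern_rate >= 0, background_rate >= 0,
            duration_ms > 0, interval_ms >= 0)
  if (length(probabilities) != n || any(probabilities < 0) ||
      abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must be length n_patterns, non-negative, sum to 1")

  shared <- round(overlap_fraction * group_size)
  stride <- group_size - shared
  K <- group_size + (n - 1L) * stride
  membership <- matrix(FALSE, K, n)
  for (j in seq_len(n)) {
    start <- (j - 1L) * stride
    membership[start + seq_len(group_size), j] <- TRUE
  }

  structure(list(n_patterns = n, group_size = as.integer(group_size),
                 overlap_fraction = overlap_fraction,
                 pattern_rate = pattern_rate,
                 background_rate = background_rate,
                 duration_ms = duration_ms, interval_ms = interval_ms,
                 probabilities = probabilities, order = order,
                 n_inputs = K, membership = membership),
            class = "pattern_spec")
}

#' Motion-coherence stimulation protocol for the decision task
#'
#' Two input pools, R and L, of `group_size` neurons each
#' (`K = 2 * group_size`). A stimulus with coherence `Coh` in
#' `[-0.5, +0.5]` drives the R pool at `(Coh + 0.5) * r_max` Hz and the L
#' pool at `(-Coh + 0.5) * r_max` Hz; between stimuli all inputs fire at
#' `background_rate`. Training uses fully coherent stimuli
#' (`Coh = +0.5` for "R", `-0.5` for "L") presented with
#' `probabilities = c(R, L)`.
#'
#' @inheritParams pattern_spec
#' @param r_max maximum pool rate (Hz).
#' @param probabilities named or ordered pair `(R, L)` of training
#'   presentation probabilities.
#' @return an object of class `coherence_spec` (also a `pattern_spec`:
#'   pattern 1 is the R stimulus, pattern 2 the L stimulus).
#' @examples
#' coherence_spec(probabilities = c(0.8, 0.2))  # the biased protocol
#' @export
coherence_spec <- function(group_size = 100, r_max = 50,
                           background_rate = 2, duration_ms = 100,
                           interval_ms = 100,
                           probabilities = c(0.5, 0.5)) {
  spec <- pattern_spec(2, group_size = group_size, pattern_rate = r_max,
                       background_rate = background_rate,
                       duration_ms = duration_ms, interval_ms = interval_ms,
                       probabilities = probabilities)
  spec$r_max <- r_max
  class(spec) <- c("coherence_spec", "pattern_spec")
  spec
}

#' Pool rates for a motion-coherence stimulus
#'
#' @param coh coherence in `[-0.5, +0.5]`; positive favours rightward.
#' @param r_max maximum pool rate (Hz).
#' @return named vector `c(R =, L =)` of rates in `[0, r_max]`.
#' @examples
#' coherence_rates(0.5)   # c(R = 50, L = 0)
#' coherence_rates(0)     # c(R = 25, L = 25)
#' @export
coherence_rates <- function(coh, r_max = 50) {
  if (abs(coh) > 0.5) stop("coherence must lie in [-0.5, 0.5]")
  c(R = (coh + 0.5) * r_max, L = (-coh + 0.5) * r_max)
}

#' Conditioned two-subnetwork stimulation protocol
#'
#' Two interacting subnetworks: subnetwork A receives stimuli S1/S2 drawn
#' from `a_probabilities`; simultaneously subnetwork B receives S3/S4 drawn
#' from the row of `cond_table` selected by the A-stimulus. The default
#' table is `P(S3|S1) = 1/3, P(S4|S1) = 2/3` and the mirror for S2.
#'
#' @inheritParams pattern_spec
#' @param cond_table 2 x 2 matrix of conditional probabilities, rows S1/S2
#'   (each summing to 1), columns S3/S4.
#' @param a_probabilities marginal probabilities of S1/S2.
#' @return an object of class `conditioned_spec` (a 4-pattern
#'   `pattern_spec`: patterns 1-2 feed subnetwork A, 3-4 subnetwork B).
#' @export
conditioned_spec <- function(cond_table = matrix(c(1/3, 2/3, 2/3, 1/3), 2, 2,
                                                 byrow = TRUE),
                             a_probabilities = c(0.5, 0.5), group_size = 100,
                             pattern_rate = 50, background_rate = 2,
                             duration_ms = 100, interval_ms = 100) {
  cond_table <- as.matrix(cond_table)
  if (!identical(dim(cond_table), c(2L, 2L)) || any(cond_table < 0) ||
      any(abs(rowSums(cond_table) - 1) > 1e-8))
    stop("cond_table must be 2 x 2 with rows summing to 1")
  stopifnot(length(a_probabilities) == 2,
            abs(sum(a_probabilities) - 1) < 1e-8)
  marg_b <- drop(a_probabilities %*% cond_table)
  spec <- pattern_spec(4, group_size = group_size,
                       pattern_rate = pattern_rate,
                       background_rate = background_rate,
                       duration_ms = duration_ms, interval_ms = interval_ms,
                       probabilities = c(a_probabilities / 2, marg_b / 2))
  spec$cond_table <- cond_table
  spec$a_probabilities <- a_probabilities
  class(spec) <- c("conditioned_spec", "pattern_spec")
  spec
}

new_schedule <- function(events, spec, total_ms) {
  structure(list(events = events, spec = spec, total_ms = total_ms),
            class = "stimulus_schedule")
}

#' Build a stimulus schedule
#'
#' Tiles `[0, total_ms)` with alternating gaps and pattern presentations
#' (gap first), drawing pattern identities i.i.d. from the spec's
#' probabilities (or cycling them for `order = "fixed_sequence"`). For a
#' [conditioned_spec()] each presentation slot carries one A-pattern and,
#' time-aligned with it, one B-pattern drawn from the conditional table.
#' Identities are drawn from the current RNG stream.
#'
#' @param spec a [pattern_spec()] (or subclass).
#' @param total_ms schedule length (ms).
#' @param jitter_ms if `> 0`, gap lengths are drawn uniformly from
#'   `interval_ms` plus/minus this jitter (the default constant-interval
#'   protocol is the `0` case; irregular intervals do not change the
#'   learning outcomes).
#' @return an object of class `stimulus_schedule`; `$events` is a data
#'   frame with columns `pattern_id`, `onset_ms`, `offset_ms` (for
#'   conditioned specs, B-events appear as additional rows with ids 3/4 at
#'   the same onsets as their A-events).
#' @examples
#' set.seed(1)
#' sched <- build_schedule(pattern_spec(2), total_ms = 2000)
#' head(sched$events)
#' @export
build_schedule <- function(spec, total_ms, jitter_ms = 0) {
  stopifnot(inherits(spec, "pattern_spec"), total_ms > 0,
            jitter_ms >= 0, jitter_ms <= spec$interval_ms)
  cycle <- spec$duration_ms + spec$interval_ms
  n_ev <- floor(total_ms / cycle)
  if (n_ev < 1) stop("total_ms too short for a single presentation")
  gaps <- if (jitter_ms > 0) {
    round(stats::runif(n_ev, spec$interval_ms - jitter_ms,
                       spec$interval_ms + jitter_ms))
  } else rep(spec$interval_ms, n_ev)
  onsets <- cumsum(gaps) + (seq_len(n_ev) - 1) * spec$duration_ms
  onsets <- onsets[onsets + spec$duration_ms <= total_ms]
  n_ev <- length(onsets)
  if (n_ev < 1) stop("total_ms too short for a single presentation")

  if (inherits(spec, "conditioned_spec")) {
    a_id <- sample.int(2L, n_ev, replace = TRUE, prob = spec$a_probabilities)
    b_id <- integer(n_ev)
    for (a in 1:2) {
      idx <- which(a_id == a)
      if (length(idx))
        b_id[idx] <- 2L + sample.int(2L, length(idx), replace = TRUE,
                                     prob = spec$cond_table[a, ])
    }
    events <- data.frame(
      pattern_id = c(rbind(a_id, b_id)),
      onset_ms = rep(onsets, each = 2),
      offset_ms = rep(onsets + spec$duration_ms, each = 2))
  } else {
    ids <- if (spec$order == "fixed_sequence") {
      rep_len(seq_len(spec$n_patterns), n_ev)
    } else {
      sample.int(spec$n_patterns, n_ev, replace = TRUE,
                 prob = spec$probabilities)
    }
    events <- data.frame(pattern_id = ids, onset_ms = onsets,
                         offset_ms = onsets + spec$duration_ms)
  }
  new_schedule(events, spec, total_ms)
}

#' @rdname build_schedule
#' @details `build_conditioned_schedule()` is the conditioned-protocol
#'   entry point; it requires a [conditioned_spec()] and is otherwise
#'   identical to `build_schedule()`.
#' @export
build_conditioned_schedule <- function(spec, total_ms, jitter_ms = 0) {
  stopifnot(inherits(spec, "conditioned_spec"))
  build_schedule(spec, total_ms, jitter_ms)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: %d events over %g ms (%d input neurons)\n",
              nrow(x$events), x$total_ms, x$spec$n_inputs))
  print(utils::head(x$events, 4))
  invisible(x)
}

#' Empirical pattern frequencies of a schedule
#' @param schedule a `stimulus_schedule`.
#' @return named vector of presentation frequencies per pattern id.
#' @export
empirical_frequencies <- function(schedule) {
  tab <- tabulate(schedule$events$pattern_id, schedule$spec$n_patterns)
  stats::setNames(tab / sum(tab), seq_along(tab))
}

new_rate_program <- function(rates, program, dt, t0 = 0) {
  stopifnot(is.matrix(rates), all(rates >= 0),
            all(program >= 1), all(program <= ncol(rates)))
  structure(list(rates = rates, program = as.integer(program), dt = dt,
                 n_steps = length(program)),
            class = "rate_program")
}

#' Per-neuron rate program of a schedule
#'
#' Expands a schedule into a compact per-step rate program: a K x P matrix
#' of rate columns plus one column index per time step. During a pattern
#' presentation the pattern's member neurons fire at the pattern rate and
#' all others at the background rate; outside presentations every input
#' neuron fires at the background rate. For a [coherence_spec()] the two
#' training columns are the fully coherent stimuli (the non-driven pool is
#' silent, not at background). For a [conditioned_spec()] the A- and
#' B-patterns active in the same slot are combined into one column.
#'
#' @param schedule a [build_schedule()] result.
#' @param dt time step (ms).
#' @return an object of class `rate_program`.
#' @export
schedule_to_rates <- function(schedule, dt = 1) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  spec <- schedule$spec
  K <- spec$n_inputs
  n_steps <- floor(schedule$total_ms / dt)
  ev <- schedule$events

  pattern_column <- function(ids) {
    # rate column with the given pattern(s) active
    col <- rep(spec$background_rate, K)
    for (id in ids) {
      r <- if (inherits(spec, "coherence_spec")) {
        # fully coherent training stimulus: opposite pool silent
        cr <- coherence_rates(if (id == 1L) 0.5 else -0.5, spec$r_max)
        col[] <- 0
        if (id == 1L) cr[["R"]] else cr[["L"]]
      } else spec$pattern_rate
      col[spec$membership[, id]] <- r
    }
    col
  }

  if (inherits(spec, "conditioned_spec")) {
    # one column per (A, B) combination
    combos <- expand.grid(a = 1:2, b = 3:4)
    rates <- cbind(rep(spec$background_rate, K),
                   vapply(seq_len(nrow(combos)),
                          function(i) pattern_column(unlist(combos[i, ])),
                          numeric(K)))
    program <- rep(1L, n_steps)
    a_rows <- ev[ev$pattern_id <= 2L, ]
    b_rows <- ev[ev$pattern_id >= 3L, ]
    for (i in seq_len(nrow(a_rows))) {
      from <- floor(a_rows$onset_ms[i] / dt) + 1L
      to <- min(ceiling(a_rows$offset_ms[i] / dt), n_steps)
      combo <- which(combos$a == a_rows$pattern_id[i] &
                       combos$b == b_rows$pattern_id[i])
      if (from <= to) program[from:to] <- 1L + combo
    }
  } else {
    rates <- cbind(rep(spec$background_rate, K),
                   vapply(seq_len(spec$n_patterns), pattern_column,
                          numeric(K)))
    program <- rep(1L, n_steps)
    for (i in seq_len(nrow(ev))) {
      from <- floor(ev$onset_ms[i] / dt) + 1L
      to <- min(ceiling(ev$offset_ms[i] / dt), n_steps)
      if (from <= to) program[from:to] <- ev$pattern_id[i] + 1L
    }
  }
  new_rate_program(rates, program, dt)
}

#' Constant-rate and silent programs
#'
#' `constant_program()` holds every input neuron at a fixed rate (one rate
#' per neuron or a single value); `blank_program()` is the silent program
#' used for spontaneous phases.
#'
#' @param rates rate(s) in Hz (recycled to K).
#' @param n_inputs number of input neurons K.
#' @param duration_ms program length (ms).
#' @param dt time step (ms).
#' @return a `rate_program`.
#' @export
constant_program <- function(rates, n_inputs, duration_ms, dt = 1) {
  new_rate_program(matrix(rep_len(rates, n_inputs), ncol = 1),
                   rep(1L, floor(duration_ms / dt)), dt)
}

#' @rdname constant_program
#' @export
blank_program <- function(n_inputs, duration_ms, dt = 1) {
  constant_program(0, n_inputs, duration_ms, dt)
}

#' Poisson input raster from a rate program
#'
#' Bernoulli thinning at probability `rate * dt / 1000` per neuron per
#' step, drawn column by column from the current RNG stream (the same
#' order the simulation engine consumes input randomness).
#'
#' @param program a `rate_program`, or a K x steps matrix of rates (Hz).
#' @param dt time step (ms), taken from the program if one is given.
#' @return logical K x steps spike matrix.
#' @export
rates_to_spikes <- function(program, dt = 1) {
  if (inherits(program, "rate_program")) {
    rmat <- program$rates[, program$program, drop = FALSE]
    dt <- program$dt
  } else rmat <- as.matrix(program)
  stopifnot(all(rmat >= 0), all(rmat * dt / 1000 <= 1))
  out <- matrix(stats::runif(length(rmat)), nrow(rmat)) < rmat * dt / 1000
  out
}
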