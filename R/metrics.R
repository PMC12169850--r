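#' Assign neurons to cell assemblies from evoked responses
#'
#' Each neuron is assigned to the stimulus that drives it most strongly in
#' a post-learning probe (plasticity off, trial-averaged rates). Neurons
#' whose selectivity index `(max - second_max) / (max + second_max)` falls
#' below `threshold` stay unassigned; ties resolve to the lowest stimulus
#' id.
#'
#' @param evoked_rates N x S matrix of trial-averaged evoked rates (Hz),
#'   one column per stimulus.
#' @param threshold selectivity threshold in `[0, 1)`.
#' @return an object of class `assembly_assignment`: integer vector
#'   (length N, `NA` = unassigned) with attributes `selectivity` and
#'   `n_assemblies`.
#' @examples
#' assign_assemblies(rbind(c(40, 2, 2), c(10, 10, 10)))  # 1, NA
#' @export
assign_assemblies <- function(evoked_rates, threshold = 0.3) {
  er <- as.matrix(evoked_rates)
  S <- ncol(er)
  stopifnot(S >= 2, threshold >= 0, threshold < 1)
  if (all(er == 0)) {
    warning("all evoked responses are zero; every neuron unassigned")
    return(structure(rep(NA_integer_, nrow(er)),
                     selectivity = rep(0, nrow(er)), n_assemblies = S,
                     class = "assembly_assignment"))
  }
  best <- apply(er, 1, which.max)
  sel <- apply(er, 1, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (s[1] + s[2] == 0) 0 else (s[1] - s[2]) / (s[1] + s[2])
  })
  asg <- ifelse(sel >= threshold, best, NA_integer_)
  structure(as.integer(asg), selectivity = sel, n_assemblies = S,
            class = "assembly_assignment")
}

#' @export
print.assembly_assignment <- function(x, ...) {
  n <- attr(x, "n_assemblies")
  cat("Assembly assignment:", length(x), "neurons,", n, "assemblies\n")
  cat("  sizes:", paste(tabulate(x, n), collapse = ", "),
      " unassigned:", sum(is.na(x)), "\n")
  invisible(x)
}

assembly_members <- function(assignment, j) which(assignment == j)

#' Assembly sizes of an assignment
#' @param assignment an [assign_assemblies()] result.
#' @return integer vector of member counts per assembly.
#' @export
assembly_sizes <- function(assignment) {
  tabulate(assignment[!is.na(assignment)], attr(assignment, "n_assemblies"))
}

#' Population activity of each assembly
#'
#' Sums per-neuron rates over the members of each assembly (unassigned
#' neurons are excluded).
#'
#' @param rates per-neuron rates (Hz).
#' @param assignment an [assign_assemblies()] result.
#' @return numeric vector of population rates, one per assembly.
#' @export
population_activity <- function(rates, assignment) {
  n <- attr(assignment, "n_assemblies")
  vapply(seq_len(n),
         function(j) sum(rates[assembly_members(assignment, j)]), 0)
}

ratio_to_others <- function(values, target) {
  stopifnot(target >= 1, target <= length(values))
  others <- values[-target]
  if (any(!is.finite(values)) || length(others) == 0 || mean(others) <= 0)
    return(NA_real_)
  values[target] / mean(others)
}

#' Replay ratio metrics of a target assembly
#'
#' Three scalar summaries of how a target assembly compares with the
#' average of the others:
#' \itemize{
#'   \item `firing_rate_ratio()`: mean single-neuron rate in the target
#'     assembly over the mean of the other assemblies' mean rates.
#'   \item `assembly_size_ratio()`: member count over the mean of the
#'     other counts.
#'   \item `assembly_activity_ratio()`: population (summed) rate over the
#'     mean of the other population rates; for spontaneous epochs this is
#'     the probability-readout statistic that should match the training
#'     probability ratio.
#' }
#' Empty competitor assemblies make the ratio undefined (`NA`).
#'
#' @param rates per-neuron rates (Hz) over the analysis epoch.
#' @param assignment an [assign_assemblies()] result.
#' @param target target assembly id (default 1).
#' @return a scalar ratio, or `NA` if undefined.
#' @examples
#' asg <- assign_assemblies(diag(5) * 40)
#' assembly_activity_ratio(c(4, 2, 2, 2, 2), asg)  # 2
#' @name ratio_metrics
NULL

#' @rdname ratio_metrics
#' @export
firing_rate_ratio <- function(rates, assignment, target = 1) {
  n <- attr(assignment, "n_assemblies")
  means <- vapply(seq_len(n), function(j) {
    m <- assembly_members(assignment, j)
    if (length(m) == 0) NA_real_ else mean(rates[m])
  }, 0)
  ratio_to_others(means, target)
}

#' @rdname ratio_metrics
#' @export
assembly_size_ratio <- function(rates, assignment, target = 1) {
  sizes <- assembly_sizes(assignment)
  if (any(sizes == 0)) return(NA_real_)
  ratio_to_others(sizes, target)
}

#' @rdname ratio_metrics
#' @export
assembly_activity_ratio <- function(rates, assignment, target = 1) {
  pops <- population_activity(rates, assignment)
  if (any(assembly_sizes(assignment) == 0)) return(NA_real_)
  ratio_to_others(pops, target)
}

#' Activity ratio and psychometric readout of the decision task
#'
#' `activity_ratio_AR()` is the fraction of the total population rate
#' carried by the R-encoding assembly, `r_R / (r_R + r_L)`;
#' `choices_to_right()` converts it to the model's choice percentage,
#' `AR * 100`.
#'
#' @param r_R_pop,r_L_pop population rates of the R- and L-encoding
#'   assemblies (Hz), non-negative and not both zero.
#' @return `activity_ratio_AR()`: a fraction in `[0, 1]`;
#'   `choices_to_right()`: a percentage.
#' @examples
#' activity_ratio_AR(4, 1)          # 0.8
#' choices_to_right(activity_ratio_AR(1, 1))  # 50
#' @export
activity_ratio_AR <- function(r_R_pop, r_L_pop) {
  stopifnot(r_R_pop >= 0, r_L_pop >= 0)
  if (r_R_pop + r_L_pop == 0) return(NA_real_)
  r_R_pop / (r_R_pop + r_L_pop)
}

#' @rdname activity_ratio_AR
#' @param AR an activity ratio in `[0, 1]`.
#' @export
choices_to_right <- function(AR) AR * 100

#' Normalized within-assembly excitatory incoming weights
#'
#' For each assembly, sums the positive entries of the recurrent matrix
#' whose pre- and postsynaptic neurons both belong to that assembly, then
#' normalizes across assemblies to sum to 1. After training with unequal
#' stimulus probabilities these fractions approximate the empirical
#' stimulus probabilities.
#'
#' @param M recurrent weight matrix (rows = postsynaptic).
#' @param assignment an [assign_assemblies()] result.
#' @return numeric vector of fractions summing to 1 (`NA` if no positive
#'   within-assembly weight exists).
#' @export
normalized_excitatory_incoming_weights <- function(M, assignment) {
  n <- attr(assignment, "n_assemblies")
  stopifnot(n >= 2)
  sums <- vapply(seq_len(n), function(j) {
    m <- assembly_members(assignment, j)
    blk <- M[m, m, drop = FALSE]
    sum(blk[blk > 0])
  }, 0)
  if (sum(sums) <= 0) {
    warning("no positive within-assembly weights")
    return(rep(NA_real_, n))
  }
  sums / sum(sums)
}

#' Effective lateral inhibition between excitatory neurons
#'
#' In the Dale's-law model, inhibition reaches excitatory neurons
#' disynaptically: E -> I (via `M_IE`) -> E (via one of the two `G`
#' paths). The effective E-to-E inhibition of a path is the matrix product
#' `G_path %*% M_IE`.
#'
#' @param G_path N_E x N_I inhibitory matrix of one path onto E neurons.
#' @param M_IE N_I x N_E excitatory matrix onto the inhibitory pool.
#' @return N_E x N_E effective inhibition matrix.
#' @export
lateral_inhibition_matrix <- function(G_path, M_IE) {
  if (ncol(G_path) != nrow(M_IE)) stop("incompatible shapes")
  G_path %*% M_IE
}

#' Within- vs between-assembly summary of a connectivity matrix
#'
#' Medians and quartiles of the entries whose pre- and postsynaptic
#' neurons share (within) or do not share (between) an assembly;
#' unassigned neurons are excluded, as are diagonal self-terms.
#'
#' @param mat square connectivity matrix.
#' @param assignment an [assign_assemblies()] result (or integer vector).
#' @return data frame with rows `within` and `between`.
#' @export
within_between_summary <- function(mat, assignment) {
  asg <- as.integer(assignment)
  ok <- !is.na(asg)
  same <- outer(asg, asg, "==")
  same[!ok, ] <- NA; same[, !ok] <- NA
  diag(same) <- NA
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  out <- rbind(within = qs(mat[which(same)]),
               between = qs(mat[which(!same)]))
  data.frame(class = rownames(out), q25 = out[, 1], median = out[, 2],
             q75 = out[, 3], row.names = NULL)
}

#' Pairwise correlations of binned spike counts
#'
#' Pearson correlation of per-neuron spike counts in fixed bins. Pairs
#' involving a zero-variance neuron get correlation 0 and are flagged in
#' the `zero_variance` attribute.
#'
#' @param bins N x n_bins matrix of spike counts (e.g. from
#'   [run_phase()]'s `bin_ms` recording), at least 100 bins.
#' @return N x N correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(bins) {
  stopifnot(is.matrix(bins), ncol(bins) >= 100)
  zv <- apply(bins, 1, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(bins)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "zero_variance") <- which(zv)
  cc
}

#' Mean within- and between-assembly correlation
#'
#' @param corr_mat correlation matrix from [pairwise_correlations()].
#' @param assignment an [assign_assemblies()] result.
#' @return named vector `c(within =, between =)`.
#' @export
assembly_correlation_contrast <- function(corr_mat, assignment) {
  asg <- as.integer(assignment)
  same <- outer(asg, asg, "==")
  same[is.na(same)] <- NA
  diag(same) <- NA
  c(within = mean(corr_mat[which(same)]),
    between = mean(corr_mat[which(!same)]))
}

#' Prediction-error traces of a run
#'
#' Extracts the per-connection-class mean absolute prediction error
#' `|f - phi(v_class)|` against time from a phase recording (or a fitted
#' model's training log). Used to compare control and ablated runs: intact
#' inhibitory plasticity keeps late-time errors small and stable.
#'
#' @param rec a `phase_recording` with traces (see [run_phase()]'s
#'   `trace_ms`), or a fitted [replaynet()] object.
#' @return data frame with columns `t_ms`, `err_W`, `err_M`, `err_G`.
#' @export
prediction_error_trace <- function(rec) {
  tr <- if (inherits(rec, "phase_recording")) rec$traces
        else if (!is.null(rec$training_log)) rec$training_log
        else stop("no traces recorded")
  if (is.null(tr)) stop("no traces recorded")
  tr[, c("t_ms", "err_W", "err_M", "err_G")]
}
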